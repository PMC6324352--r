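#' @title Patient-year claims: readers, cohort assembly, descriptive summaries
#' @description Functions for getting delimited-text claims (diagnoses, costs,
#'   demographics) into a validated patient-year cohort, mirroring the data
#'   flow of dual-payer (VA + Medicare) utilization studies.
#' @name claims_data
NULL

default_claims_schema <- function() {
  list(
    diagnoses    = c(patient_id = "patient_id", code = "code",
                     service_date = "service_date", source = "source"),
    costs        = c(patient_id = "patient_id", payer = "payer",
                     amount = "amount", year = "year"),
    demographics = c(patient_id = "patient_id", age = "age", sex = "sex",
                     ltc_days = "ltc_days", medication_only = "medication_only",
                     any_va_use = "any_va_use")
  )
}

read_table_checked <- function(path, want, sep = ",") {
  if (!file.exists(path)) {
    stop_rc("claims file not found: %s", path, class = "riskcalib_io_error")
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE)
  missing <- setdiff(unname(want), names(df))
  if (length(missing) > 0) {
    stop_rc("schema error in %s: missing column(s) %s", basename(path),
            paste(missing, collapse = ", "), class = "riskcalib_schema_error")
  }
  out <- df[, unname(want), drop = FALSE]
  names(out) <- names(want)
  out
}

#' Read delimited-text claims files
#'
#' Parses the three claim tables (diagnosis events, cost records,
#' demographics) from comma-separated text with a header row. Diagnosis codes
#' are normalized (dots stripped, upper-cased). Rows with unparseable dates,
#' negative or non-numeric amounts, or invalid enum values are rejected and
#' collected in a line-numbered report rather than aborting the read; a
#' missing column is a hard schema error naming the column.
#'
#' @param diagnoses_path,costs_path,demographics_path file paths.
#' @param schema optional column mapping, a list with elements `diagnoses`,
#'   `costs`, `demographics`, each a named character vector mapping the
#'   canonical field name to the column name in the file. Defaults to the
#'   canonical names themselves.
#' @param sep field separator (default comma).
#' @return a list with data frames `diagnoses` (patient_id, code,
#'   service_date, source), `costs` (patient_id, payer, amount in dollars,
#'   year), `demographics`, and `report`, a list with `n_rejected` and a data
#'   frame `errors` (file, line, message). File line numbers count the header
#'   as line 1.
#' @export
read_claims <- function(diagnoses_path, costs_path, demographics_path,
                        schema = NULL, sep = ",") {
  sch <- default_claims_schema()
  if (!is.null(schema)) {
    for (nm in names(schema)) sch[[nm]][names(schema[[nm]])] <- schema[[nm]]
  }
  errors <- list()
  note <- function(file, line, message) {
    errors[[length(errors) + 1L]] <<- data.frame(
      file = file, line = line, message = message, stringsAsFactors = FALSE)
  }

  dx <- read_table_checked(diagnoses_path, sch$diagnoses, sep)
  dx$code <- normalize_code(dx$code)
  dx$source <- toupper(dx$source)
  dx_date <- as.Date(dx$service_date, format = "%Y-%m-%d")
  ok <- !is.na(dx_date) & nzchar(dx$code) & dx$source %in% c("VA", "MEDICARE")
  for (i in which(!ok)) {
    note(basename(diagnoses_path), i + 1L,
         if (is.na(dx_date[i])) sprintf("unparseable date '%s'", dx$service_date[i])
         else if (!nzchar(dx$code[i])) "empty diagnosis code"
         else sprintf("unknown source '%s'", dx$source[i]))
  }
  dx <- dx[ok, , drop = FALSE]
  dx$service_date <- dx_date[ok]

  co <- read_table_checked(costs_path, sch$costs, sep)
  co$payer <- toupper(co$payer)
  amt <- suppressWarnings(as.numeric(co$amount))
  yr <- suppressWarnings(as.integer(co$year))
  ok <- is.finite(amt) & amt >= 0 & !is.na(yr) &
    co$payer %in% c("VA", "MEDICARE_A", "MEDICARE_B", "MEDICARE_D")
  for (i in which(!ok)) {
    note(basename(costs_path), i + 1L,
         if (!is.finite(amt[i]) || is.na(amt[i])) sprintf("unparseable amount '%s'", co$amount[i])
         else if (amt[i] < 0) sprintf("negative amount %s", co$amount[i])
         else if (is.na(yr[i])) sprintf("unparseable year '%s'", co$year[i])
         else sprintf("unknown payer '%s'", co$payer[i]))
  }
  co <- co[ok, , drop = FALSE]
  co$amount <- amt[ok]
  co$year <- yr[ok]

  de <- read_table_checked(demographics_path, sch$demographics, sep)
  age <- suppressWarnings(as.numeric(de$age))
  ltc <- suppressWarnings(as.integer(de$ltc_days))
  sex <- toupper(de$sex)
  ok <- is.finite(age) & age >= 0 & sex %in% c("M", "F") &
    !is.na(ltc) & ltc >= 0 & ltc <= 366
  for (i in which(!ok)) {
    note(basename(demographics_path), i + 1L, "invalid demographics row")
  }
  de <- de[ok, , drop = FALSE]
  de$age <- age[ok]
  de$sex <- sex[ok]
  de$ltc_days <- ltc[ok]
  de$medication_only <- toupper(de$medication_only) %in% c("TRUE", "T", "1", "YES")
  de$any_va_use <- toupper(de$any_va_use) %in% c("TRUE", "T", "1", "YES")

  err_df <- if (length(errors)) do.call(rbind, errors) else
    data.frame(file = character(), line = integer(), message = character(),
               stringsAsFactors = FALSE)
  list(diagnoses = dx, costs = co, demographics = de,
       report = list(n_rejected = nrow(err_df), errors = err_df))
}

#' Assemble a patient-year cohort
#'
#' Applies the study-population rules to parsed claims: drops
#' medication-only patients and patients with no VA use, restricts diagnosis
#' events to the diagnosis year (the year before the cost year), and sums
#' each patient's costs for the cost year across payers, splitting VA from
#' Medicare (Parts A, B, D). Costs are carried as integer cents so that
#' `total = VA + Medicare` holds exactly.
#'
#' @param claims a list with `diagnoses`, `costs`, `demographics` as returned
#'   by [read_claims()].
#' @param cost_year integer year whose costs are analyzed.
#' @param diagnosis_year integer year supplying diagnoses; must equal
#'   `cost_year - 1`.
#' @return an object of class `claims_cohort`: a list with `patients` (one
#'   row per patient: demographics, `va_cents`, `medicare_cents`,
#'   `total_cents`, `ltc_days`, exclusion flags), `diagnoses` (events in the
#'   diagnosis year for retained patients), `cost_year`, `diagnosis_year`,
#'   and `exclusions`, counts of patients dropped by each rule.
#' @export
assemble_cohort <- function(claims, cost_year, diagnosis_year = cost_year - 1L) {
  if (diagnosis_year != cost_year - 1L) {
    stop_rc("diagnosis_year (%d) must be cost_year - 1 (%d)",
            diagnosis_year, cost_year - 1L, class = "riskcalib_config_error")
  }
  de <- claims$demographics
  if (anyDuplicated(de$patient_id)) {
    stop_rc("duplicate patient_id in demographics", class = "riskcalib_schema_error")
  }
  n_med_only <- sum(de$medication_only)
  n_no_va <- sum(!de$any_va_use & !de$medication_only)
  keep <- !de$medication_only & de$any_va_use
  de <- de[keep, , drop = FALSE]
  if (nrow(de) == 0) {
    stop_rc("cohort empty after exclusions", class = "riskcalib_empty_cohort")
  }

  co <- claims$costs
  co <- co[co$year == cost_year & co$patient_id %in% de$patient_id, , drop = FALSE]
  co$cents <- dollars_to_cents(co$amount)
  is_va <- co$payer == "VA"
  va <- rowsum(co$cents[is_va], co$patient_id[is_va])
  mc <- rowsum(co$cents[!is_va], co$patient_id[!is_va])
  de$va_cents <- as.integer(va[match(de$patient_id, rownames(va))])
  de$va_cents[is.na(de$va_cents)] <- 0L
  de$medicare_cents <- as.integer(mc[match(de$patient_id, rownames(mc))])
  de$medicare_cents[is.na(de$medicare_cents)] <- 0L
  de$total_cents <- de$va_cents + de$medicare_cents

  dx <- claims$diagnoses
  dx <- dx[as.integer(format(dx$service_date, "%Y")) == diagnosis_year &
             dx$patient_id %in% de$patient_id, , drop = FALSE]

  structure(
    list(patients = de[, c("patient_id", "age", "sex", "ltc_days",
                           "medication_only", "any_va_use",
                           "va_cents", "medicare_cents", "total_cents")],
         diagnoses = dx,
         cost_year = as.integer(cost_year),
         diagnosis_year = as.integer(diagnosis_year),
         exclusions = c(medication_only = n_med_only, no_va_use = n_no_va)),
    class = "claims_cohort")
}

#' @export
print.claims_cohort <- function(x, ...) {
  cat(sprintf("claims_cohort: %d patients, cost year %d (diagnoses %d), %d diagnosis events\n",
              nrow(x$patients), x$cost_year, x$diagnosis_year, nrow(x$diagnoses)))
  invisible(x)
}

#' Patient table of a cohort, with costs in dollars
#'
#' @param cohort a `claims_cohort`.
#' @return the `patients` data frame with `va_cost`, `medicare_cost`,
#'   `total_cost` columns in dollars.
#' @export
cohort_patients <- function(cohort) {
  p <- cohort$patients
  p$va_cost <- cents_to_dollars(p$va_cents)
  p$medicare_cost <- cents_to_dollars(p$medicare_cents)
  p$total_cost <- cents_to_dollars(p$total_cents)
  p
}

#' Prevalence percentage as printed in descriptive tables
#'
#' `100 * count / denominator`, rounded half away from zero to one decimal.
#'
#' @param count,denominator non-negative counts.
#' @return numeric percentage.
#' @export
#' @examples
#' prevalence_pct(694706, 5472629)  # 12.7
prevalence_pct <- function(count, denominator) {
  round_half_away(100 * count / denominator, 1L)
}

#' Descriptive cohort summary stratified by age 65
#'
#' Builds the standard sample-characteristics table: overall and stratified
#' by age < 65 vs >= 65 at the start of the cost year, it reports n, percent
#' male, mean (SD) age, count and prevalence for each supplied condition
#' flag, and mean (SD) / median (IQR) of total, VA, and Medicare costs.
#' Percentages are rounded half away from zero to one decimal.
#'
#' @param cohort a `claims_cohort`.
#' @param flags optional named list of logical vectors aligned with
#'   `cohort$patients` rows (e.g. condition indicators from the risk engine
#'   or the psychiatric grouper).
#' @param scores optional numeric risk-score vector aligned with patients;
#'   adds a mean (SD) score row.
#' @return a data frame in long form: `characteristic`, `statistic`,
#'   `overall`, `ge65`, `lt65`.
#' @export
summarize_cohort <- function(cohort, flags = list(), scores = NULL) {
  p <- cohort_patients(cohort)
  if (nrow(p) == 0) stop_rc("empty cohort", class = "riskcalib_empty_cohort")
  strata <- list(overall = rep(TRUE, nrow(p)), ge65 = p$age >= 65, lt65 = p$age < 65)
  row <- function(characteristic, statistic, f) {
    vals <- vapply(strata, function(s) f(p[s, , drop = FALSE], s), numeric(1))
    data.frame(characteristic = characteristic, statistic = statistic,
               overall = vals[[1]], ge65 = vals[[2]], lt65 = vals[[3]],
               stringsAsFactors = FALSE)
  }
  out <- list(
    row("n", "count", function(q, s) nrow(q)),
    row("male", "count", function(q, s) sum(q$sex == "M")),
    row("male", "pct", function(q, s) prevalence_pct(sum(q$sex == "M"), nrow(q))),
    row("age", "mean", function(q, s) mean(q$age)),
    row("age", "sd", function(q, s) stats::sd(q$age))
  )
  for (nm in names(flags)) {
    fl <- flags[[nm]]
    stopifnot(length(fl) == nrow(p))
    out <- c(out,
      list(row(nm, "count", function(q, s) sum(fl[s])),
           row(nm, "pct", function(q, s) prevalence_pct(sum(fl[s]), sum(s)))))
  }
  for (cc in c("total_cost", "va_cost", "medicare_cost")) {
    cc_local <- cc
    out <- c(out, list(
      row(cc_local, "mean", function(q, s) mean(q[[cc_local]])),
      row(cc_local, "sd", function(q, s) stats::sd(q[[cc_local]])),
      row(cc_local, "median", function(q, s) stats::median(q[[cc_local]])),
      row(cc_local, "q1", function(q, s) unname(stats::quantile(q[[cc_local]], 0.25))),
      row(cc_local, "q3", function(q, s) unname(stats::quantile(q[[cc_local]], 0.75)))))
  }
  if (!is.null(scores)) {
    stopifnot(length(scores) == nrow(p))
    out <- c(out, list(
      row("risk_score", "mean", function(q, s) mean(scores[s])),
      row("risk_score", "sd", function(q, s) stats::sd(scores[s]))))
  }
  do.call(rbind, out)
}

#' Write the three claims tables as delimited text
#'
#' Inverse of [read_claims()]: emits `diagnoses.csv`, `costs.csv`,
#' `demographics.csv` under `dir` in the canonical column layout.
#'
#' @param claims list with `diagnoses`, `costs`, `demographics` data frames.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_claims <- function(claims, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("diagnoses.csv", "costs.csv", "demographics.csv"))
  dx <- claims$diagnoses
  dx$service_date <- format(dx$service_date, "%Y-%m-%d")
  utils::write.csv(dx, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(claims$costs[, c("patient_id", "payer", "amount", "year")],
                   paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(claims$demographics[, c("patient_id", "age", "sex", "ltc_days",
                                           "medication_only", "any_va_use")],
                   paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
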