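#' @title 47-category psychiatric case-mix grouper
#' @description Classifies diagnosis codes into a 47-category psychiatric
#'   case-mix system, derives named condition flags (any MH/SA, PTSD, mood
#'   disorder, serious mental illness, substance abuse, dementia, ...), and
#'   quantifies the psychiatric diagnoses a 4-category HCC risk model fails
#'   to capture.
#' @name psycms_grouper
NULL

#' Construct and validate a psychiatric code list
#'
#' @param categories data frame with columns `category_id`, `category_name`;
#'   must contain exactly 47 rows.
#' @param codes data frame with columns `code` (normalized diagnosis code)
#'   and `category_id`; a code may map to several categories.
#' @param flag_definitions named list; each element is a character vector of
#'   `category_id`s whose union defines the flag.
#' @return an object of class `psycms_codelist`.
#' @export
psycms_codelist <- function(categories, codes, flag_definitions) {
  categories$category_id <- as.character(categories$category_id)
  codes$category_id <- as.character(codes$category_id)
  codes$code <- normalize_code(codes$code)
  if (nrow(categories) != 47L || anyDuplicated(categories$category_id)) {
    stop_rc("psychiatric code list must define exactly 47 distinct categories (got %d)",
            length(unique(categories$category_id)), class = "riskcalib_spec_error")
  }
  bad <- setdiff(codes$category_id, categories$category_id)
  if (length(bad) > 0) {
    stop_rc("code list references unknown categories: %s",
            paste(unique(bad), collapse = ", "), class = "riskcalib_spec_error")
  }
  for (nm in names(flag_definitions)) {
    bad <- setdiff(flag_definitions[[nm]], categories$category_id)
    if (length(bad) > 0) {
      stop_rc("flag '%s' references unknown categories: %s", nm,
              paste(bad, collapse = ", "), class = "riskcalib_spec_error")
    }
  }
  structure(list(categories = categories, codes = codes,
                 flag_definitions = flag_definitions),
            class = "psycms_codelist")
}

#' @export
print.psycms_codelist <- function(x, ...) {
  cat(sprintf("psycms_codelist: 47 categories, %d codes, %d flags (%s)\n",
              nrow(x$codes), length(x$flag_definitions),
              paste(names(x$flag_definitions), collapse = ", ")))
  invisible(x)
}

#' Load a psychiatric code list from disk
#'
#' Expects `codes.csv` (columns code, category_id, category_name) and
#' `manifest.json` holding the 47 category names and the flag definitions.
#'
#' @param dir directory holding the code list bundle.
#' @return a validated `psycms_codelist`.
#' @export
load_psycms_codelist <- function(dir) {
  cpath <- file.path(dir, "codes.csv")
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(cpath) || !file.exists(mpath)) {
    stop_rc("psychiatric code list bundle incomplete under %s", dir,
            class = "riskcalib_io_error")
  }
  codes <- utils::read.csv(cpath, stringsAsFactors = FALSE,
                           colClasses = "character")
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  categories <- data.frame(category_id = names(man$categories),
                           category_name = unname(unlist(man$categories)),
                           stringsAsFactors = FALSE)
  flags <- lapply(man$flag_definitions, as.character)
  psycms_codelist(categories, codes[, c("code", "category_id")], flags)
}

#' Write a psychiatric code list bundle
#'
#' @param codelist a `psycms_codelist`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_psycms_codelist <- function(codelist, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  codes <- codelist$codes
  codes$category_name <- codelist$categories$category_name[
    match(codes$category_id, codelist$categories$category_id)]
  utils::write.csv(codes, file.path(dir, "codes.csv"), row.names = FALSE)
  cats <- as.list(stats::setNames(codelist$categories$category_name,
                                  codelist$categories$category_id))
  jsonlite::write_json(list(categories = cats,
                            flag_definitions = codelist$flag_definitions),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Classify one patient's diagnoses into psychiatric categories
#'
#' @param codes character vector of diagnosis codes (or data frame with a
#'   `code` column); unmapped codes are ignored.
#' @param codelist a `psycms_codelist`.
#' @return an object of class `psycms_profile`: `categories` (sorted ids)
#'   and `flags` (named logical vector, one per flag definition).
#' @export
classify <- function(codes, codelist) {
  if (is.data.frame(codes)) codes <- codes$code
  codes <- normalize_code(codes)
  cats <- sort(unique(codelist$codes$category_id[codelist$codes$code %in% codes]))
  flags <- vapply(codelist$flag_definitions,
                  function(def) length(intersect(cats, def)) > 0, logical(1))
  structure(list(categories = cats, flags = flags), class = "psycms_profile")
}

#' Classify every patient in a cohort (vectorized)
#'
#' @param cohort a `claims_cohort`.
#' @param codelist a `psycms_codelist`.
#' @return an object of class `psycms_profiles`: `flags` (data frame, one
#'   row per patient in cohort order: `patient_id` plus one logical column
#'   per flag definition) and `categories` (long data frame patient_id /
#'   category_id).
#' @export
classify_cohort <- function(cohort, codelist) {
  p <- cohort$patients
  dx <- cohort$diagnoses
  m <- merge(dx[, c("patient_id", "code")], codelist$codes, by = "code")
  cats <- unique(m[, c("patient_id", "category_id")])
  flags <- data.frame(patient_id = p$patient_id, stringsAsFactors = FALSE)
  for (nm in names(codelist$flag_definitions)) {
    def <- codelist$flag_definitions[[nm]]
    hit <- unique(cats$patient_id[cats$category_id %in% def])
    flags[[nm]] <- p$patient_id %in% hit
  }
  structure(list(flags = flags, categories = cats), class = "psycms_profiles")
}

#' @export
print.psycms_profiles <- function(x, ...) {
  cat(sprintf("psycms_profiles: %d patients, %d with any psychiatric category\n",
              nrow(x$flags), sum(x$flags$any_mh_sa %||% NA)))
  invisible(x)
}

#' Psychiatric diagnoses missed by the risk model
#'
#' The missed population is defined as patients with at least one
#' psychiatric case-mix category but no mental-health/substance-use HCC in
#' their risk profile. Categories are counted within that population and
#' ranked by count (ties broken alphabetically by category name); percents
#' use the missed population as denominator and may sum to more than 100
#' because categories overlap.
#'
#' @param hcc_profiles an `hcc_profiles` object for the cohort.
#' @param psycms_profiles a `psycms_profiles` object for the same cohort.
#' @param codelist the `psycms_codelist` used for classification.
#' @param top_n number of rows to keep (default 10; `Inf` for all).
#' @return an object of class `missed_diagnosis_table`: `denominator` and a
#'   data frame `rows` (category_id, category_name, count, pct with pct
#'   rounded half away from zero to 1 decimal). A denominator of zero yields
#'   an empty table, not an error.
#' @export
missed_mh_analysis <- function(hcc_profiles, psycms_profiles, codelist,
                               top_n = 10L) {
  fl <- psycms_profiles$flags
  pr <- hcc_profiles$profiles
  stopifnot(identical(fl$patient_id, pr$patient_id))
  missed_ids <- fl$patient_id[fl$any_mh_sa & !pr$has_mh_hcc]
  denom <- length(missed_ids)
  cats <- psycms_profiles$categories
  cats <- cats[cats$patient_id %in% missed_ids, , drop = FALSE]
  if (denom == 0L || nrow(cats) == 0L) {
    rows <- data.frame(category_id = character(), category_name = character(),
                       count = integer(), pct = numeric(), stringsAsFactors = FALSE)
  } else {
    tab <- table(cats$category_id)
    rows <- data.frame(category_id = names(tab), count = as.integer(tab),
                       stringsAsFactors = FALSE)
    rows$category_name <- codelist$categories$category_name[
      match(rows$category_id, codelist$categories$category_id)]
    rows <- rows[order(-rows$count, rows$category_name), , drop = FALSE]
    rows <- utils::head(rows, top_n)
    rows$pct <- round_half_away(100 * rows$count / denom, 1L)
    rows <- rows[, c("category_id", "category_name", "count", "pct")]
    rownames(rows) <- NULL
  }
  structure(list(denominator = denom, rows = rows),
            class = "missed_diagnosis_table")
}

#' @export
print.missed_diagnosis_table <- function(x, ...) {
  cat(sprintf("missed_diagnosis_table: %d patients with psychiatric diagnoses not captured by the risk model\n",
              x$denominator))
  if (nrow(x$rows)) print(x$rows, row.names = FALSE)
  invisible(x)
}

#' Write a missed-diagnosis table as delimited text
#'
#' @param x a `missed_diagnosis_table`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_missed_table <- function(x, path) {
  df <- x$rows
  df$denominator <- x$denominator
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
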