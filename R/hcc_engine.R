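#' @title Specification-driven HCC risk scoring
#' @description A table-driven implementation of hierarchical condition
#'   category (HCC) risk scoring: diagnosis codes are mapped to condition
#'   categories, disease hierarchies suppress less severe categories when a
#'   dominant one is present, and the risk score is the demographic
#'   coefficient plus the sum of the retained categories' coefficients, using
#'   either the community or the institutional coefficient table (the latter
#'   for patients with more than 90 days of skilled-nursing/long-term care).
#'   The engine is fully specification-driven so any published coefficient
#'   bundle in the documented file layout can be dropped in.
#' @name hcc_engine
NULL

#' Construct and validate a risk model specification
#'
#' @param icd_to_cc data frame with columns `code` (normalized diagnosis
#'   code) and `cc` (condition category id); a code may map to several
#'   categories.
#' @param hierarchies data frame with columns `dominant`, `suppressed`; one
#'   row per (dominant, suppressed) pair.
#' @param demographic_cells data frame with columns `sex`, `age_lo`,
#'   `age_hi`, `community`, `institutional`; bands are half-open `(lo, hi]`
#'   and must not overlap within a sex.
#' @param cc_coefficients data frame with columns `cc`, `community`,
#'   `institutional`.
#' @param mh_hccs character vector of condition categories designated
#'   mental-health/substance-use.
#' @param scale `"dollar"` if coefficients are on the cost scale,
#'   `"relative"` for relative risk factors.
#' @return an object of class `risk_model_spec`.
#' @export
risk_model_spec <- function(icd_to_cc, hierarchies, demographic_cells,
                            cc_coefficients, mh_hccs, scale = "dollar") {
  icd_to_cc$code <- normalize_code(icd_to_cc$code)
  icd_to_cc$cc <- as.character(icd_to_cc$cc)
  cc_coefficients$cc <- as.character(cc_coefficients$cc)
  hierarchies$dominant <- as.character(hierarchies$dominant)
  hierarchies$suppressed <- as.character(hierarchies$suppressed)
  mh_hccs <- as.character(mh_hccs)

  known <- cc_coefficients$cc
  referenced <- unique(c(hierarchies$dominant, hierarchies$suppressed, mh_hccs,
                         icd_to_cc$cc))
  unknown <- setdiff(referenced, known)
  if (length(unknown) > 0) {
    stop_rc("model spec references condition categories with no coefficient: %s",
            paste(unknown, collapse = ", "), class = "riskcalib_spec_error")
  }
  bad <- !is.finite(cc_coefficients$community) | !is.finite(cc_coefficients$institutional)
  if (any(bad)) {
    stop_rc("missing coefficient for cc %s",
            paste(cc_coefficients$cc[bad], collapse = ", "),
            class = "riskcalib_spec_error")
  }
  cyc <- find_hierarchy_cycle(hierarchies)
  if (!is.null(cyc)) {
    stop_rc("hierarchy rules contain a cycle: %s", paste(cyc, collapse = " -> "),
            class = "riskcalib_spec_error")
  }
  for (s in unique(demographic_cells$sex)) {
    b <- demographic_cells[demographic_cells$sex == s, , drop = FALSE]
    b <- b[order(b$age_lo), , drop = FALSE]
    if (any(b$age_hi <= b$age_lo) ||
        (nrow(b) > 1 && any(b$age_lo[-1] < b$age_hi[-nrow(b)]))) {
      stop_rc("demographic bands overlap or are degenerate for sex %s", s,
              class = "riskcalib_spec_error")
    }
  }
  structure(list(icd_to_cc = icd_to_cc, hierarchies = hierarchies,
                 demographic_cells = demographic_cells,
                 cc_coefficients = cc_coefficients,
                 mh_hccs = mh_hccs, scale = scale),
            class = "risk_model_spec")
}

# depth-first search over dominant -> suppressed edges; returns one cycle
# (as a vector of cc ids) or NULL
find_hierarchy_cycle <- function(hierarchies) {
  adj <- split(hierarchies$suppressed, hierarchies$dominant)
  state <- new.env(parent = emptyenv())
  path <- character()
  visit <- function(v) {
    st <- get0(v, envir = state, ifnotfound = 0L)
    if (st == 1L) return(c(path[which(path == v)[1]:length(path)], v))
    if (st == 2L) return(NULL)
    assign(v, 1L, envir = state)
    path <<- c(path, v)
    for (w in adj[[v]] %||% character()) {
      cyc <- visit(w)
      if (!is.null(cyc)) return(cyc)
    }
    path <<- path[-length(path)]
    assign(v, 2L, envir = state)
    NULL
  }
  for (v in names(adj)) {
    cyc <- visit(v)
    if (!is.null(cyc)) return(cyc)
  }
  NULL
}

#' @export
print.risk_model_spec <- function(x, ...) {
  cat(sprintf(
    "risk_model_spec: %d codes -> %d condition categories, %d hierarchy pairs, %d MH/SA categories, %s scale\n",
    length(unique(x$icd_to_cc$code)), nrow(x$cc_coefficients),
    nrow(x$hierarchies), length(x$mh_hccs), x$scale))
  invisible(x)
}

#' Load a risk model specification bundle from disk
#'
#' The bundle is a directory of delimited-text tables (`icd_to_cc.csv`,
#' `hierarchies.csv`, `demographic_cells.csv`, `cc_coefficients.csv`) plus a
#' JSON `manifest.json` holding the coefficient `scale` and the `mh_hccs`
#' list. All [risk_model_spec()] invariants are checked at load time.
#'
#' @param dir bundle directory.
#' @return a validated `risk_model_spec`.
#' @export
load_model_spec <- function(dir) {
  need <- file.path(dir, c("icd_to_cc.csv", "hierarchies.csv",
                           "demographic_cells.csv", "cc_coefficients.csv",
                           "manifest.json"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0) {
    stop_rc("model spec bundle incomplete, missing: %s",
            paste(basename(missing), collapse = ", "),
            class = "riskcalib_io_error")
  }
  rd <- function(p, classes) utils::read.csv(p, stringsAsFactors = FALSE,
                                             colClasses = classes)
  man <- jsonlite::read_json(need[5], simplifyVector = TRUE)
  risk_model_spec(
    icd_to_cc = rd(need[1], c(code = "character", cc = "character")),
    hierarchies = rd(need[2], c(dominant = "character", suppressed = "character")),
    demographic_cells = rd(need[3], NA),
    cc_coefficients = rd(need[4], c(cc = "character", community = "numeric",
                                    institutional = "numeric")),
    mh_hccs = man$mh_hccs, scale = man$scale %||% "dollar")
}

#' Write a risk model specification bundle
#'
#' @param spec a `risk_model_spec`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_model_spec <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(spec$icd_to_cc, file.path(dir, "icd_to_cc.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(spec$hierarchies, file.path(dir, "hierarchies.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(spec$demographic_cells, file.path(dir, "demographic_cells.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(spec$cc_coefficients, file.path(dir, "cc_coefficients.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(scale = spec$scale, mh_hccs = spec$mh_hccs),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Map diagnosis codes to condition categories
#'
#' Union over all events of the code-to-category lookups; codes with no
#' mapping are counted, never an error (real claims always contain codes the
#' model does not use).
#'
#' @param codes character vector of normalized diagnosis codes, or a data
#'   frame with a `code` column.
#' @param spec a `risk_model_spec`.
#' @return list with `ccs` (sorted character vector of categories) and
#'   `n_unmapped` (number of input codes with no mapping).
#' @export
map_diagnoses <- function(codes, spec) {
  if (is.data.frame(codes)) codes <- codes$code
  codes <- normalize_code(codes)
  hit <- codes %in% spec$icd_to_cc$code
  ccs <- sort(unique(spec$icd_to_cc$cc[spec$icd_to_cc$code %in% codes]))
  list(ccs = ccs, n_unmapped = sum(!hit))
}

#' Impose disease hierarchies on a condition-category set
#'
#' Rules are applied once each, in severity (topological) order, against the
#' evolving category set — the convention of published HCC software, where a
#' category that has itself been suppressed no longer suppresses anything.
#' With rules A>B and B>C, the input {A, B, C} therefore yields {A, C}: A
#' removes B, and the suppressed B leaves C alone. The result is a fixed
#' point (re-application changes nothing) and always a subset of the input.
#'
#' @param ccs character vector of condition categories (pre-hierarchy).
#' @param spec a `risk_model_spec`.
#' @return character vector of retained categories (HCCs), sorted.
#' @export
impose_hierarchies <- function(ccs, spec) {
  active <- ccs
  for (i in hierarchy_topo_order(spec$hierarchies)) {
    if (spec$hierarchies$dominant[i] %in% active) {
      active <- setdiff(active, spec$hierarchies$suppressed[i])
    }
  }
  sort(active)
}

# rule indices ordered so a rule's dominant is settled (never suppressed by
# a later rule) before the rule fires; well-defined because the graph is
# acyclic
hierarchy_topo_order <- function(h) {
  if (nrow(h) == 0) return(integer(0))
  nodes <- unique(c(h$dominant, h$suppressed))
  depth <- stats::setNames(rep(0L, length(nodes)), nodes)
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (i in seq_len(nrow(h))) {
      need <- depth[[h$dominant[i]]] + 1L
      if (depth[[h$suppressed[i]]] < need) {
        depth[[h$suppressed[i]]] <- need
        changed <- TRUE
      }
    }
  }
  order(depth[h$dominant])
}

#' Demographic coefficient lookup
#'
#' Bands are half-open `(age_lo, age_hi]`: an age equal to a band's upper
#' edge belongs to that band.
#'
#' @param age age in years at the start of the cost year.
#' @param sex `"M"` or `"F"`.
#' @param variant `"COMMUNITY"` or `"INSTITUTIONAL"`.
#' @param spec a `risk_model_spec`.
#' @return the scalar coefficient of the unique band containing (sex, age).
#' @export
demographic_coefficient <- function(age, sex, variant, spec) {
  co <- demographic_coefficient_vec(age, sex, variant, spec)
  if (is.na(co)) {
    stop_rc("no demographic band covers sex=%s age=%s", sex, format(age),
            class = "riskcalib_no_band_error")
  }
  co
}

demographic_coefficient_vec <- function(age, sex, variant, spec) {
  cells <- spec$demographic_cells
  out <- rep(NA_real_, length(age))
  variant <- rep_len(variant, length(age))
  for (i in seq_len(nrow(cells))) {
    inband <- sex == cells$sex[i] & age > cells$age_lo[i] & age <= cells$age_hi[i]
    out[inband] <- ifelse(variant[inband] == "INSTITUTIONAL",
                          cells$institutional[i], cells$community[i])
  }
  out
}

#' Compute the risk score for one patient-year record
#'
#' The institutional coefficient table is used iff the patient spent more
#' than 90 days in skilled nursing / long-term care (`ltc_days > 90`;
#' exactly 90 days is community). The score is linear additive: demographic
#' coefficient plus the sum of the post-hierarchy category coefficients.
#'
#' @param record list or one-row data frame with `patient_id`, `age`, `sex`,
#'   `ltc_days`, and `codes` (character vector of diagnosis codes).
#' @param spec a `risk_model_spec`.
#' @return an object of class `hcc_profile`: `patient_id`, `raw_ccs`,
#'   `hccs`, `variant`, `score`, `n_unmapped`.
#' @export
compute_risk_score <- function(record, spec) {
  mapped <- map_diagnoses(record$codes %||% character(), spec)
  hccs <- impose_hierarchies(mapped$ccs, spec)
  variant <- if (record$ltc_days > 90) "INSTITUTIONAL" else "COMMUNITY"
  demog <- demographic_coefficient(record$age, record$sex, variant, spec)
  cc_col <- if (variant == "INSTITUTIONAL") "institutional" else "community"
  idx <- match(hccs, spec$cc_coefficients$cc)
  cc_sum <- sum(spec$cc_coefficients[[cc_col]][idx[!is.na(idx)]])
  structure(list(patient_id = record$patient_id, raw_ccs = mapped$ccs,
                 hccs = hccs, variant = variant,
                 score = demog + cc_sum, n_unmapped = mapped$n_unmapped),
            class = "hcc_profile")
}

#' @export
print.hcc_profile <- function(x, ...) {
  cat(sprintf("hcc_profile %s [%s]: score %.2f, HCCs {%s}\n", x$patient_id,
              x$variant, x$score, paste(x$hccs, collapse = ", ")))
  invisible(x)
}

#' Does a profile carry a mental-health/substance-use HCC?
#'
#' @param profile an `hcc_profile`.
#' @param spec a `risk_model_spec`.
#' @return `TRUE` iff the post-hierarchy category set intersects the model's
#'   designated MH/SA categories.
#' @export
has_mh_hcc <- function(profile, spec) {
  length(intersect(profile$hccs, spec$mh_hccs)) > 0
}

#' Score every patient in a cohort (vectorized)
#'
#' Bulk equivalent of [compute_risk_score()]; identical results, one pass
#' over the diagnosis table instead of one lookup per patient.
#'
#' @param cohort a `claims_cohort`.
#' @param spec a `risk_model_spec`.
#' @return an object of class `hcc_profiles`: list with `profiles` (data
#'   frame: `patient_id`, `variant`, `score`, `has_mh_hcc`, ordered as the
#'   cohort), `hccs` and `raw_ccs` (long data frames patient_id/cc), and
#'   `n_unmapped`, the total count of diagnosis events whose code has no
#'   mapping.
#' @export
score_cohort <- function(cohort, spec) {
  p <- cohort$patients
  dx <- cohort$diagnoses
  hit <- dx$code %in% spec$icd_to_cc$code
  n_unmapped <- sum(!hit)
  m <- merge(dx[hit, c("patient_id", "code")], spec$icd_to_cc, by = "code")
  raw <- unique(m[, c("patient_id", "cc")])

  # hierarchy imposition in severity order against the evolving per-patient
  # sets (same semantics as impose_hierarchies, applied column-wise)
  cc_levels <- spec$cc_coefficients$cc
  act <- matrix(FALSE, nrow(p), length(cc_levels),
                dimnames = list(NULL, cc_levels))
  act[cbind(match(raw$patient_id, p$patient_id), match(raw$cc, cc_levels))] <- TRUE
  for (i in hierarchy_topo_order(spec$hierarchies)) {
    dom <- spec$hierarchies$dominant[i]
    sup <- spec$hierarchies$suppressed[i]
    act[act[, dom], sup] <- FALSE
  }
  idx <- which(act, arr.ind = TRUE)
  hccs <- data.frame(patient_id = p$patient_id[idx[, 1]],
                     cc = cc_levels[idx[, 2]], stringsAsFactors = FALSE)

  variant <- ifelse(p$ltc_days > 90, "INSTITUTIONAL", "COMMUNITY")
  demog <- demographic_coefficient_vec(p$age, p$sex, variant, spec)
  if (anyNA(demog)) {
    i <- which(is.na(demog))[1]
    stop_rc("no demographic band covers sex=%s age=%s", p$sex[i], format(p$age[i]),
            class = "riskcalib_no_band_error")
  }
  if (nrow(hccs) > 0) {
    cc_idx <- match(hccs$cc, spec$cc_coefficients$cc)
    pat_variant <- variant[match(hccs$patient_id, p$patient_id)]
    coef <- ifelse(pat_variant == "INSTITUTIONAL",
                   spec$cc_coefficients$institutional[cc_idx],
                   spec$cc_coefficients$community[cc_idx])
    cc_sum <- rowsum(coef, hccs$patient_id)
    at <- match(p$patient_id, rownames(cc_sum))
    score <- demog + ifelse(is.na(at), 0, cc_sum[at])
  } else {
    score <- demog
  }
  mh_pat <- unique(hccs$patient_id[hccs$cc %in% spec$mh_hccs])
  structure(list(
    profiles = data.frame(patient_id = p$patient_id, variant = variant,
                          score = as.numeric(score),
                          has_mh_hcc = p$patient_id %in% mh_pat,
                          stringsAsFactors = FALSE),
    hccs = hccs, raw_ccs = raw, n_unmapped = n_unmapped),
    class = "hcc_profiles")
}

#' @export
print.hcc_profiles <- function(x, ...) {
  cat(sprintf("hcc_profiles: %d patients, mean score %.2f, %d with MH/SA HCC, %d unmapped events\n",
              nrow(x$profiles), mean(x$profiles$score),
              sum(x$profiles$has_mh_hcc), x$n_unmapped))
  invisible(x)
}
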