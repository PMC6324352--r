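#' @title Decile-of-predicted-cost calibration
#' @description Goodness-of-fit tables comparing mean predicted ("expected")
#'   with mean actual cost by decile of predicted cost, for a full cohort or
#'   a clinical subgroup (deciles are recomputed within the subgroup), plus
#'   the base-vs-augmented improvement series. The sign convention is
#'   gap = expected − actual: negative gaps are underestimates.
#' @name calibration
NULL

#' Assign deciles of predicted cost
#'
#' Patients are sorted by `(prediction, patient_id)` ascending and split
#' into 10 contiguous groups with sizes as equal as possible: the first
#' `n %% 10` groups receive the extra patient. Tie-breaking on patient id
#' makes the assignment deterministic.
#'
#' @param predictions numeric vector of predicted costs.
#' @param patient_id identifiers used to break ties (default positional).
#' @return integer vector of decile labels 1..10 in the input order.
#' @export
assign_deciles <- function(predictions, patient_id = seq_along(predictions)) {
  n <- length(predictions)
  if (n < 10L) {
    stop_rc("at least 10 patients are required to form deciles (got %d)", n,
            class = "riskcalib_decile_error")
  }
  ord <- order(predictions, patient_id)
  base <- n %/% 10L
  extra <- n %% 10L
  sizes <- rep(base, 10L) + c(rep(1L, extra), rep(0L, 10L - extra))
  dec <- rep(1:10, times = sizes)
  out <- integer(n)
  out[ord] <- dec
  out
}

#' Per-decile calibration table
#'
#' If a subgroup is given, the cohort is FIRST restricted to it and deciles
#' are recomputed within the subgroup (subgroup tables therefore have their
#' own expected-cost ranges). Expected and actual decile means are
#' unweighted; the dollar gap is expected − actual; the percent gap is
#' `100 * gap / expected`, rounded half away from zero to the nearest
#' integer.
#'
#' @param cohort a `claims_cohort` or a numeric vector of actual costs.
#' @param predictions numeric vector of predicted costs, aligned.
#' @param subgroup optional logical vector selecting the subgroup.
#' @param label cohort label carried in the output.
#' @return an object of class `calibration_table`: `label`, `n`, and
#'   `deciles`, a data frame with columns `decile`, `n`, `expected`,
#'   `actual`, `gap`, `pct`.
#' @export
calibration_table <- function(cohort, predictions, subgroup = NULL,
                              label = "cohort") {
  y <- extract_costs(cohort)
  ids <- if (inherits(cohort, "claims_cohort")) cohort$patients$patient_id
         else seq_along(y)
  stopifnot(length(predictions) == length(y))
  if (!is.null(subgroup)) {
    stopifnot(length(subgroup) == length(y))
    y <- y[subgroup]; predictions <- predictions[subgroup]; ids <- ids[subgroup]
  }
  if (length(y) < 10L) {
    stop_rc("subgroup too small to form deciles (n = %d)", length(y),
            class = "riskcalib_decile_error")
  }
  dec <- assign_deciles(predictions, ids)
  expected <- as.numeric(tapply(predictions, dec, mean))
  actual <- as.numeric(tapply(y, dec, mean))
  gap <- decile_gap(expected, actual)
  structure(list(
    label = label, n = length(y),
    deciles = data.frame(decile = 1:10,
                         n = as.integer(table(dec)),
                         expected = expected, actual = actual,
                         gap = gap, pct = gap_pct(gap, expected))),
    class = "calibration_table")
}

#' Calibration gap and percent-gap arithmetic
#'
#' The dollar gap is `expected - actual` (positive = overestimate); the
#' percent gap divides by the expected mean and rounds half away from zero
#' to the nearest integer, the convention of the published decile tables.
#'
#' @param expected,actual per-decile mean predicted and mean actual cost.
#' @param gap per-decile dollar gap.
#' @return numeric vector.
#' @export
decile_gap <- function(expected, actual) expected - actual

#' @rdname decile_gap
#' @export
gap_pct <- function(gap, expected) round_half_away(100 * gap / expected, 0L)

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("calibration_table '%s' (n = %d):\n", x$label, x$n))
  print(x$deciles, row.names = FALSE)
  invisible(x)
}

#' Base-vs-augmented improvement series
#'
#' Computes, for each model's own deciles of predicted cost, the per-decile
#' dollar gap, and summarizes the improvement as
#' `mean(|gap|) base − mean(|gap|) augmented` (positive = the augmented
#' model calibrates better).
#'
#' @param cohort a `claims_cohort` or numeric vector of actual costs.
#' @param predictions_base,predictions_augmented aligned prediction vectors
#'   from the two models.
#' @param subgroup optional logical subgroup selector (applied first).
#' @return list with `deciles` (data frame: decile, gap_base,
#'   gap_augmented) and `reduction`.
#' @export
improvement_series <- function(cohort, predictions_base,
                               predictions_augmented, subgroup = NULL) {
  if (length(predictions_base) != length(predictions_augmented)) {
    stop_rc("prediction vectors are not on the same cohort",
            class = "riskcalib_design_error")
  }
  tb <- calibration_table(cohort, predictions_base, subgroup, label = "base")
  ta <- calibration_table(cohort, predictions_augmented, subgroup,
                          label = "augmented")
  list(deciles = data.frame(decile = 1:10,
                            gap_base = tb$deciles$gap,
                            gap_augmented = ta$deciles$gap),
       reduction = mean(abs(tb$deciles$gap)) - mean(abs(ta$deciles$gap)))
}

#' Write a calibration table as delimited text
#'
#' Columns follow the published layout: decile, expected, actual, gap, pct.
#'
#' @param x a `calibration_table`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_calibration <- function(x, path) {
  df <- x$deciles
  df$label <- x$label
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
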