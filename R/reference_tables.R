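#' Published reference tables
#'
#' Aggregate numbers from a published national evaluation of the V21 risk
#' model in a 5.47M-patient veteran cohort, shipped as plain-text fixtures:
#' the per-decile expected/actual cost means for the full cohort and the
#' diabetes, mental-health, and dementia subgroups, and the printed
#' prevalence counts (cohort characteristics and the top-10
#' missed-psychiatric-diagnosis table). Used to verify the package's gap and
#' percentage arithmetic against printed values; the patient-level data
#' behind them are not public and are emulated by [generate_cohort()].
#'
#' @return `reference_decile_fit()`: data frame with cohort, n, decile,
#'   expected, actual, printed_gap, printed_pct. `reference_prevalence()`:
#'   data frame with table, characteristic, count, denominator,
#'   printed_pct.
#' @export
reference_decile_fit <- function() {
  utils::read.csv(system.file("extdata", "reference", "decile_fit.csv",
                              package = "riskcalib"),
                  stringsAsFactors = FALSE)
}

#' @rdname reference_decile_fit
#' @export
reference_prevalence <- function() {
  utils::read.csv(system.file("extdata", "reference", "prevalence.csv",
                              package = "riskcalib"),
                  stringsAsFactors = FALSE)
}
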