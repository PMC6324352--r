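#' Round half away from zero
#'
#' Commercial rounding as used in published claims tables: ties go away from
#' zero (`round_half_away(-104.5) == -105`), unlike [base::round()]'s
#' round-half-even. All percentage columns in this package use it.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_away(c(0.25, -0.25), 1)   # 0.3, -0.3
#' round_half_away(12.695, 1)           # 12.7
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Normalize an ICD-9-style diagnosis code
#'
#' Strips dots and whitespace and upper-cases, so dotted ("296.1") and
#' undotted ("2961") dialects compare equal.
#'
#' @param code character vector of diagnosis codes.
#' @return character vector of normalized codes.
#' @export
normalize_code <- function(code) {
  toupper(gsub("[.[:space:]]", "", as.character(code)))
}

# dollars <-> integer cents; cents keep the payer-additivity invariant exact
dollars_to_cents <- function(x) as.integer(round(x * 100))
cents_to_dollars <- function(x) x / 100

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_rc <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "riskcalib_error")))
}

# format a mean (SD) / median (IQR) pair the way descriptive tables print them
fmt_mean_sd <- function(x) {
  sprintf("%.1f (%.1f)", mean(x), stats::sd(x))
}
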