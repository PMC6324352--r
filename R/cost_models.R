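#' @title Cost regressions: OLS, square-root OLS, gamma log-link GLM
#' @description Fits annual total cost on the scalar risk score, optionally
#'   augmented with the 47 psychiatric category indicators, under three
#'   families: plain OLS (the payment-formula scale), OLS on the square-root
#'   of cost with Duan smearing retransformation, and a gamma GLM with log
#'   link. Skewed, heteroskedastic cost data are the norm here, so robust
#'   (HC1) coefficient covariances are carried alongside the classical ones.
#' @name cost_models
NULL

model_families <- c("ols_linear", "ols_sqrt", "glm_gamma_log")

# design matrix: intercept, score, then the 47 indicators in the code list's
# fixed category order
build_design <- function(scores, psycms_profiles = NULL, codelist = NULL) {
  X <- cbind(`(Intercept)` = 1, score = scores)
  if (!is.null(psycms_profiles)) {
    if (is.null(codelist)) {
      stop_rc("codelist required to order the psychiatric indicators",
              class = "riskcalib_design_error")
    }
    fl <- psycms_profiles$flags
    cats <- psycms_profiles$categories
    ind <- matrix(0, nrow = nrow(fl), ncol = nrow(codelist$categories),
                  dimnames = list(NULL, codelist$categories$category_id))
    if (nrow(cats)) {
      i <- match(cats$patient_id, fl$patient_id)
      j <- match(cats$category_id, colnames(ind))
      ok <- !is.na(i) & !is.na(j)
      ind[cbind(i[ok], j[ok])] <- 1
    }
    X <- cbind(X, ind)
  }
  X
}

extract_costs <- function(cohort) {
  if (inherits(cohort, "claims_cohort")) cents_to_dollars(cohort$patients$total_cents)
  else as.numeric(cohort)
}

#' Fit a cost regression
#'
#' @param cohort a `claims_cohort`, or directly a numeric vector of total
#'   costs in dollars.
#' @param scores numeric risk-score vector aligned with the cohort.
#' @param psycms_profiles optional `psycms_profiles` for the augmented
#'   design (score plus 47 psychiatric indicators); `NULL` for the base
#'   design.
#' @param codelist the `psycms_codelist` (required with `psycms_profiles`;
#'   fixes the indicator column order).
#' @param family one of `"ols_linear"`, `"ols_sqrt"`, `"glm_gamma_log"`.
#' @param zero_floor for the gamma family, costs below this are floored to
#'   it (default $1); the number floored is reported in `diagnostics`.
#' @return an object of class `cost_model`: coefficients, classical and
#'   HC1-robust standard errors, `n`, `r_squared` on the fitting scale (for
#'   `ols_sqrt`, `r_squared_response` additionally reports the dollar
#'   scale), `retransform_factor` (Duan smearing constant, sqrt family),
#'   and `diagnostics` (negative-prediction and floored-cost counts).
#' @details The square-root family back-transforms with Duan-type smearing:
#'   for the sqrt transform the smearing estimate of E(y|x) is
#'   `(Xb)^2 + mean(e^2)`, the mean squared residual entering as an additive
#'   constant (the OLS residuals have mean zero). The gamma GLM models the
#'   cost mean directly, so no retransformation is needed. Rank-deficient
#'   designs abort with the collinear columns named; GLM non-convergence
#'   aborts with the iteration count.
#' @export
fit_cost_model <- function(cohort, scores, psycms_profiles = NULL,
                           codelist = NULL,
                           family = c("ols_linear", "ols_sqrt", "glm_gamma_log"),
                           zero_floor = 1) {
  family <- match.arg(family)
  y <- extract_costs(cohort)
  stopifnot(length(y) == length(scores), all(is.finite(scores)))
  X <- build_design(scores, psycms_profiles, codelist)
  # an indicator for a category no cohort member has (or every member has)
  # carries no information; drop it rather than abort — its increment is
  # implicitly zero at prediction time
  dropped <- character()
  if (ncol(X) > 2) {
    novar <- c(FALSE, FALSE,
               apply(X[, -(1:2), drop = FALSE], 2, stats::var) == 0)
    dropped <- colnames(X)[novar]
    X <- X[, !novar, drop = FALSE]
  }
  if (length(y) <= ncol(X)) {
    stop_rc("n (%d) must exceed the number of design columns (%d)",
            length(y), ncol(X), class = "riskcalib_design_error")
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop_rc("rank-deficient design; collinear column(s): %s",
            paste(bad, collapse = ", "), class = "riskcalib_rank_error")
  }

  diagnostics <- list(n_negative_predictions = 0L, n_floored = 0L)
  retransform_factor <- NULL
  r2_response <- NULL
  df <- as.data.frame(X[, -1, drop = FALSE], optional = TRUE)
  names(df) <- colnames(X)[-1]

  if (family == "glm_gamma_log") {
    yfit <- y
    n_floor <- sum(yfit < zero_floor)
    yfit <- pmax(yfit, zero_floor)
    diagnostics$n_floored <- n_floor
    df$.y <- yfit
    # an exact fit makes the AIC's dgamma() NaN (zero dispersion); harmless
    fit <- suppressWarnings(
      stats::glm(.y ~ ., data = df, family = stats::Gamma(link = "log"),
                 control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
    if (!fit$converged) {
      stop_rc("gamma GLM did not converge in %d iterations", fit$iter,
              class = "riskcalib_convergence_error")
    }
    beta <- stats::coef(fit)
    yhat <- as.numeric(exp(X %*% beta))
    r2 <- 1 - sum((yfit - yhat)^2) / sum((yfit - mean(yfit))^2)
    retransform_factor <- 1
  } else {
    yfit <- if (family == "ols_sqrt") sqrt(y) else y
    df$.y <- yfit
    fit <- stats::lm(.y ~ ., data = df)
    beta <- stats::coef(fit)
    eta <- as.numeric(X %*% beta)
    if (family == "ols_sqrt") {
      retransform_factor <- mean(stats::residuals(fit)^2)
      yhat_resp <- eta^2 + retransform_factor
      r2 <- 1 - sum((yfit - eta)^2) / sum((yfit - mean(yfit))^2)
      r2_response <- 1 - sum((y - yhat_resp)^2) / sum((y - mean(y))^2)
    } else {
      r2 <- 1 - sum((y - eta)^2) / sum((y - mean(y))^2)
      diagnostics$n_negative_predictions <- sum(eta < 0)
    }
  }
  names(beta) <- colnames(X)
  # vcov on a zero-residual fit warns about a perfect fit; that is a
  # legitimate input here (exact synthetic data)
  vc_cl <- suppressWarnings(stats::vcov(fit))
  vc_hc <- suppressWarnings(sandwich::vcovHC(fit, type = "HC1"))
  dimnames(vc_cl) <- dimnames(vc_hc) <- list(colnames(X), colnames(X))
  structure(list(
    family = family, coefficients = beta,
    se_classical = sqrt(diag(vc_cl)), se_robust = sqrt(diag(vc_hc)),
    n = length(y), n_params = ncol(X),
    augmented = !is.null(psycms_profiles),
    columns = colnames(X), dropped_columns = dropped,
    r_squared = r2, r_squared_response = r2_response,
    retransform_factor = retransform_factor,
    diagnostics = diagnostics,
    y_checksum = c(n = length(y), mean = mean(y), var = stats::var(y))),
    class = "cost_model")
}

#' @export
print.cost_model <- function(x, ...) {
  cat(sprintf("cost_model [%s%s]: n = %d, %d terms, R^2 = %.4f%s\n",
              x$family, if (x$augmented) " + 47 psychiatric indicators" else "",
              x$n, x$n_params, x$r_squared,
              if (!is.null(x$r_squared_response))
                sprintf(" (response scale %.4f)", x$r_squared_response) else ""))
  invisible(x)
}

#' Predicted costs from a fitted cost model
#'
#' OLS predictions are not clipped: a linear payment formula can produce
#' negative predictions and clipping would distort decile membership.
#'
#' @param object a `cost_model`.
#' @param scores numeric risk-score vector.
#' @param psycms_profiles `psycms_profiles` if (and only if) the model was
#'   fit with the augmented design.
#' @param codelist the `psycms_codelist` used at fit time.
#' @param ... unused.
#' @return numeric vector of predicted dollar costs.
#' @export
predict.cost_model <- function(object, scores, psycms_profiles = NULL,
                               codelist = NULL, ...) {
  if (object$augmented != !is.null(psycms_profiles)) {
    stop_rc("design mismatch: model %s fitted with psychiatric indicators",
            if (object$augmented) "was" else "was not",
            class = "riskcalib_design_error")
  }
  X <- build_design(scores, psycms_profiles, codelist)
  if (!all(object$columns %in% colnames(X))) {
    stop_rc("design mismatch: expected columns %s",
            paste(utils::head(object$columns, 5), collapse = ", "),
            class = "riskcalib_design_error")
  }
  X <- X[, object$columns, drop = FALSE]
  eta <- as.numeric(X %*% object$coefficients)
  switch(object$family,
         ols_linear = eta,
         ols_sqrt = eta^2 + object$retransform_factor,
         glm_gamma_log = exp(eta))
}

#' Confidence interval for the risk-score slope
#'
#' Uses heteroskedasticity-robust (HC1) standard errors by default —
#' multiplicative cost noise makes the error variance grow with the mean,
#' and classical OLS intervals under-cover in that regime.
#'
#' @param model a `cost_model`.
#' @param parm coefficient name (default `"score"`).
#' @param level confidence level.
#' @param robust use HC1 standard errors (default) or classical.
#' @return named numeric vector `c(lower, upper)`.
#' @export
slope_confint <- function(model, parm = "score", level = 0.95, robust = TRUE) {
  se <- if (robust) model$se_robust[parm] else model$se_classical[parm]
  est <- model$coefficients[parm]
  q <- stats::qt(1 - (1 - level) / 2, df = model$n - model$n_params)
  c(lower = unname(est - q * se), upper = unname(est + q * se))
}

#' Compare a base and an augmented cost model
#'
#' Both models must be fit to the same cohort (checked through a cost
#' checksum) with the same family. For nested least-squares fits on the same
#' sample the augmented R-squared can never be below the base R-squared.
#'
#' @param model_base,model_augmented fitted `cost_model`s.
#' @return list with `family`, `r2_base`, `r2_augmented`, `difference`.
#' @export
compare_fit <- function(model_base, model_augmented) {
  if (!isTRUE(all.equal(model_base$y_checksum, model_augmented$y_checksum))) {
    stop_rc("models were fitted on different cohorts",
            class = "riskcalib_design_error")
  }
  if (model_base$family != model_augmented$family) {
    stop_rc("models use different families (%s vs %s)",
            model_base$family, model_augmented$family,
            class = "riskcalib_design_error")
  }
  list(family = model_base$family,
       r2_base = model_base$r_squared,
       r2_augmented = model_augmented$r_squared,
       difference = model_augmented$r_squared - model_base$r_squared)
}

#' Serialize a fitted cost model to JSON
#'
#' @param model a `cost_model`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_cost_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized cost model
#'
#' @param path JSON file written by [write_cost_model()].
#' @return a `cost_model`.
#' @export
read_cost_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$coefficients <- stats::setNames(as.numeric(x$coefficients), x$columns)
  x$se_classical <- stats::setNames(as.numeric(x$se_classical), x$columns)
  x$se_robust <- stats::setNames(as.numeric(x$se_robust), x$columns)
  x$y_checksum <- unlist(x$y_checksum)
  x$r_squared_response <- x$r_squared_response %||% NULL
  structure(x, class = "cost_model")
}
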