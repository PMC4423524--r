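#' Design matrix for the log-EFR subgroup regression
#'
#' Prepares the precision-weighted regression of `log(lambda_efr)` on sex,
#' career bin and incarceration history across the 12 non-regional subgroup
#' cells. The response is `log(lambda_efr)`; the design holds an intercept and
#' indicators for male, career 6-10, career >=11 and ever-incarcerated
#' (baselines: female, 0-5 years, never incarcerated); the weights are the
#' bootstrap precisions `1 / log_lambda_var`.
#'
#' @param estimates A tibble of subgroup estimates with columns `sex`,
#'   `career_bin`, `prison`, `lambda_efr`, `log_lambda_var` — typically
#'   `efr_table(records, keys = "regression", ...)`.
#' @return A list with `response` (numeric), `design` (matrix) and `weights`
#'   (numeric), row-aligned with `estimates`.
#' @export
efr_design <- function(estimates) {
  needed <- c("sex", "career_bin", "prison", "lambda_efr", "log_lambda_var")
  if (!all(needed %in% names(estimates))) {
    abort(paste0("`estimates` must have columns ", paste(needed, collapse = ", "), "."))
  }
  if (any(is.na(estimates$lambda_efr)) || any(estimates$lambda_efr <= 0)) {
    abort(paste0(
      "Every subgroup must have lambda_efr > 0 to regress on the log scale; ",
      "exclude or merge zero-rate subgroups before fitting."
    ))
  }
  if (any(is.na(estimates$log_lambda_var)) || any(estimates$log_lambda_var <= 0)) {
    abort("Every subgroup needs a positive bootstrap variance of log(lambda) for the precision weights.")
  }
  design <- cbind(
    "(Intercept)" = 1,
    male = as.numeric(estimates$sex == "M"),
    "career6-10" = as.numeric(estimates$career_bin == "6-10"),
    "career>=11" = as.numeric(estimates$career_bin == ">=11"),
    ever_prison = as.numeric(estimates$prison == "ever")
  )
  list(response = log(estimates$lambda_efr), design = design,
       weights = 1 / estimates$log_lambda_var)
}

#' Weighted least squares on a prepared design
#'
#' Solves the weighted normal equations via [stats::lm()], with standard
#' errors from the weighted residual variance on `n - p` degrees of freedom
#' and two-sided p-values from the t distribution.
#'
#' @param response Numeric response vector.
#' @param design Numeric design matrix (including any intercept column).
#' @param weights Positive weights.
#' @return An object of class `efr_wls`.
#' @export
wls_fit <- function(response, design, weights) {
  if (any(weights <= 0)) abort("All weights must be positive.")
  if (nrow(design) != length(response) || length(weights) != length(response)) {
    abort("`response`, `design` and `weights` must have matching lengths.")
  }
  dat <- data.frame(.y = response)
  fit <- lm(.y ~ 0 + design, data = dat, weights = weights)
  if (any(is.na(coef(fit)))) {
    bad <- sub("^design", "", names(coef(fit))[is.na(coef(fit))])
    abort(paste0("Design matrix is rank deficient; collinear terms: ",
                 paste(bad, collapse = ", "), "."))
  }
  structure(
    list(fit = fit, terms = colnames(design), weights = weights,
         n_points = length(response)),
    class = "efr_wls"
  )
}

#' Precision-weighted regression of log EFR rates on subgroup factors
#'
#' Fits the weighted linear model for `log(lambda_efr)` over the 12
#' sex x career-bin x prison subgroup cells, weighting each cell by its
#' bootstrap precision (reciprocal of the variance of log lambda over
#' replicates). Inference uses the t distribution on `n - p` residual degrees
#' of freedom (7 in the standard 12-cell configuration).
#'
#' @inheritParams efr_design
#' @return An `efr_wls` object; see [tidy.efr_wls()] and [glance.efr_wls()].
#' @examples
#' cohort <- generate_cohort(cohort_config(n_respondents = 2500, seed = 8))
#' est <- efr_table(cohort$records, keys = "regression", n_boot = 200, seed = 4)
#' fit <- efr_regression(est)
#' tidy(fit)
#' @export
efr_regression <- function(estimates) {
  d <- efr_design(estimates)
  out <- wls_fit(d$response, d$design, d$weights)
  out$estimates <- estimates
  out
}

#' @describeIn efr_regression Coefficients, standard errors, t statistics,
#'   p-values and confidence limits as a tibble.
#' @param x,object An `efr_wls` object.
#' @param conf.level Confidence level for the limits.
#' @param ... Unused.
#' @export
tidy.efr_wls <- function(x, conf.level = 0.95, ...) {
  s <- summary(x$fit)$coefficients
  df <- x$fit$df.residual
  tcrit <- qt(1 - (1 - conf.level) / 2, df)
  tibble(
    term = x$terms,
    estimate = unname(s[, 1]),
    std.error = unname(s[, 2]),
    statistic = unname(s[, 3]),
    p.value = unname(s[, 4]),
    conf.low = unname(s[, 1] - tcrit * s[, 2]),
    conf.high = unname(s[, 1] + tcrit * s[, 2])
  )
}

#' @describeIn efr_regression One-row model summary.
#' @export
glance.efr_wls <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    n_points = x$n_points,
    df.residual = x$fit$df.residual,
    r.squared = s$r.squared,
    sigma = s$sigma
  )
}

#' @export
print.efr_wls <- function(x, ...) {
  cat("Precision-weighted regression of log(lambda_EFR) on subgroup factors\n")
  cat("  n =", x$n_points, "subgroups, residual df =", x$fit$df.residual, "\n\n")
  print(as.data.frame(tidy(x)), digits = 3, row.names = FALSE)
  invisible(x)
}
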