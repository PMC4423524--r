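#' Published NESI 2008-2009 summary inputs
#'
#' Convenience constructors for the published summary statistics of Scotland's
#' Needle Exchange Surveillance Initiative (NESI) 2008-2009 injector survey,
#' used both as default calibration targets for [generate_cohort()] and as the
#' printed inputs to the replacement-rate model when the raw microdata are not
#' available.
#'
#' `nesi_initiation_cells()` returns, for each injecting-career bin crossed
#' with incarceration history (pooled over sex and region), the number of
#' respondents, past-year initiators, reported initiations, and the published
#' per-annum EFR initiation rate.
#'
#' `nesi_efr_lookup()` packages the published pooled EFR rates as an
#' [efr_lookup_table()] ready for [replacement_rate()].
#'
#' `nesi_incarceration_rates()` returns the published maximum-likelihood
#' piecewise per-annum first-incarceration rates (p1: career years 1-5,
#' p2: 6-10, p3: >=11), by sex or pooled.
#'
#' @param sex One of `"overall"`, `"female"`, `"male"`.
#' @return A tibble (`nesi_initiation_cells`, `nesi_incarceration_rates`) or an
#'   `efr_lookup_table` (`nesi_efr_lookup`).
#' @examples
#' nesi_initiation_cells()
#' nesi_incarceration_rates("male")
#' @name nesi_published
NULL

#' @rdname nesi_published
#' @export
nesi_initiation_cells <- function() {
  tibble(
    career_bin   = factor(rep(CAREER_BINS, each = 2), levels = CAREER_BINS),
    prison       = rep(c("never", "ever"), 3),
    n_respondents = c(482L, 318L, 286L, 440L, 259L, 715L),
    n_initiators  = c(102L, 82L, 40L, 69L, 23L, 127L),
    n_initiations = c(531L, 233L, 180L, 219L, 78L, 453L),
    lambda_efr    = c(0.46, 0.26, 0.22, 0.22, 0.11, 0.21)
  )
}

#' @rdname nesi_published
#' @export
nesi_efr_lookup <- function() {
  efr_lookup_table(
    lambda_never = c(0.46, 0.22, 0.11),
    lambda_ever  = c(0.26, 0.22, 0.21)
  )
}

#' @rdname nesi_published
#' @export
nesi_incarceration_rates <- function(sex = c("overall", "female", "male")) {
  sex <- match.arg(sex)
  rates <- switch(sex,
    overall = c(0.14, 0.05, 0.04),
    female  = c(0.07, 0.06, 0.04),
    male    = c(0.19, 0.05, 0.03)
  )
  setNames(rates, c("p1", "p2", "p3"))
}
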