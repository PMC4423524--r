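#' Generate a synthetic NESI-like survey cohort
#'
#' Draws a seeded respondent table with the record structure of a
#' cross-sectional injector survey: demographics, whole-year injecting-career
#' length, incarceration history, past-year injection status, the number of
#' initiations the respondent was present at in the past year, and the number
#' of *other* injectors present at the most recent initiation (respondent and
#' novice excluded; asked only of initiators). The generating parameters are
#' returned alongside the records so downstream estimators can be checked
#' against known ground truth.
#'
#' Generation follows the survey's data-generating story: career length is a
#' truncated-geometric sampling knob; the year of first incarceration `X` is
#' drawn from the sex-specific piecewise-geometric process (per-annum
#' probability p1 in career years 1-5, p2 in 6-10, p3 thereafter) and
#' `ever_incarcerated = (X <= career_years)`; initiator status is Bernoulli
#' with the cell probability for the respondent's (sex, career-bin, prison)
#' cell; initiators' counts are 1 + geometric with the cell mean, and their
#' others-present count is Poisson. Missingness is applied completely at
#' random. Identical configs (including seed) give identical cohorts.
#'
#' @param config A [cohort_config()].
#' @return A list of class `idu_cohort` with elements `records` (tibble, one
#'   row per respondent) and `truth` (the config plus a tibble of analytic
#'   per-cell expectations: initiator probability, mean count among initiators,
#'   expected mean initiations per respondent, the population per-annum EFR
#'   rate `expected_lambda` — using E\[1/(N+1)\] = (1 - exp(-mu))/mu for
#'   Poisson others — and `expected_lambda_est`, the large-sample expectation
#'   of the subgroup estimator after its exclusion of initiators with missing
#'   others-present answers).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_respondents = 200, seed = 42))
#' cohort$records
#' cohort$truth$cells
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be created by `cohort_config()`.")
  }
  config <- validate_cohort_config(config)
  n <- as.integer(config$n_respondents)

  records <- withr::with_seed(config$seed, {
    sex <- ifelse(runif(n) < config$prop_female, "F", "M")
    region <- ifelse(runif(n) < config$prop_region_ggc, "GGC", "Else")
    age_group <- ifelse(runif(n) < config$prop_age_under35, "<35", ">=35")
    career_years <- pmin(rgeom(n, config$career_cessation_gen),
                         config$career_cap_years)

    x_first <- rep(Inf, n)
    for (s in c("F", "M")) {
      i <- sex == s
      x_first[i] <- rfirst_incarceration(sum(i), config$incarceration_rates_by_sex[[s]])
    }
    ever_incarcerated <- x_first <= career_years
    injected_past_year <- runif(n) < config$prop_injected_past_year

    key <- tibble(
      sex = sex,
      career_bin = career_bin(career_years),
      prison = ifelse(ever_incarcerated, "ever", "never")
    )
    prob <- left_join(key, config$initiator_prob,
                      by = c("sex", "career_bin", "prison"))$prob
    mean_count <- left_join(key, config$initiation_count_mean,
                            by = c("sex", "career_bin", "prison"))$mean_count

    initiator <- runif(n) < prob
    n_initiations_py <- ifelse(initiator, 1L + rgeom(n, 1 / mean_count), 0L)
    n_others_recent <- ifelse(initiator, rpois(n, config$others_present_mean), NA_integer_)
    n_others_recent[initiator & runif(n) < config$missing_others_rate] <- NA_integer_

    # record-level classifier non-response: blank one demographic at random
    miss <- runif(n) < config$missing_covariate_rate
    which_cov <- sample.int(3L, n, replace = TRUE)
    sex[miss & which_cov == 1L] <- NA_character_
    region[miss & which_cov == 2L] <- NA_character_
    age_group[miss & which_cov == 3L] <- NA_character_

    tibble(
      id = sprintf("R%06d", seq_len(n)),
      sex = sex,
      region = region,
      age_group = age_group,
      career_years = as.integer(career_years),
      ever_incarcerated = ever_incarcerated,
      injected_past_year = injected_past_year,
      n_initiations_py = as.integer(n_initiations_py),
      n_others_recent = as.integer(n_others_recent)
    )
  })

  mu <- config$others_present_mean
  e_inv <- if (mu > 0) (1 - exp(-mu)) / mu else 1 # E[1/(N+1)], N ~ Poisson(mu)
  r_miss <- config$missing_others_rate
  cells <- left_join(
    config$initiator_prob, config$initiation_count_mean,
    by = c("sex", "career_bin", "prison")
  ) %>%
    mutate(
      expected_mean_initiations = .data$prob * .data$mean_count,
      expected_lambda = .data$prob * .data$mean_count * e_inv,
      # large-sample expectation of the subgroup estimator: dropping the
      # missing-others initiators removes positive contributions from both
      # numerator and denominator, deflating the mean by (1-r)/(1 - p r)
      expected_lambda_est = .data$expected_lambda * (1 - r_miss) /
        (1 - .data$prob * r_miss)
    )

  structure(
    list(records = records, truth = list(config = config, cells = cells)),
    class = "idu_cohort"
  )
}

# Inverse-CDF draw of the first-incarceration year X under piecewise-geometric
# per-annum rates (p1 years 1-5, p2 years 6-10, p3 thereafter). Returns Inf
# when the draw escapes all positive-rate pieces (possible only if p3 = 0).
rfirst_incarceration <- function(n, rates) {
  if (n == 0L) return(numeric(0))
  p <- as.numeric(rates)
  v <- runif(n)              # target survival level: X = min{x : S(x) <= v}
  lv <- log(v)
  l1 <- log1p(-p[1]); l2 <- log1p(-p[2]); l3 <- log1p(-p[3])
  c5 <- 5 * l1               # log S(5)
  c10 <- c5 + 5 * l2         # log S(10)

  x <- rep(Inf, n)
  if (p[1] > 0) {
    cand <- pmax(ceiling(lv / l1), 1)
    hit <- cand <= 5
    x[hit] <- cand[hit]
  }
  open <- is.infinite(x)
  if (p[2] > 0 && any(open)) {
    cand <- pmax(5 + ceiling((lv[open] - c5) / l2), 6)
    hit <- cand <= 10
    x[open][hit] <- cand[hit]
  }
  open <- is.infinite(x)
  if (p[3] > 0 && any(open)) {
    x[open] <- pmax(10 + ceiling((lv[open] - c10) / l3), 11)
  }
  x
}

#' @export
print.idu_cohort <- function(x, ...) {
  r <- x$records
  cat("<idu_cohort> ", nrow(r), " respondents (seed ", x$truth$config$seed, ")\n", sep = "")
  cat("  initiators: ", sum(r$n_initiations_py > 0),
      " | ever incarcerated: ", sum(r$ever_incarcerated),
      " | median career: ", stats::median(r$career_years), " years\n", sep = "")
  invisible(x)
}
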