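#' Per-respondent EFR initiation rate
#'
#' The equivalent-of-full-responsibility (EFR) rate shares responsibility for
#' each initiation equally among the injectors present: a respondent who was
#' present at `k` past-year initiations with `m` other injectors present at the
#' most recent one is assigned `k / (m + 1)` initiations per annum (the `+ 1`
#' is the respondent; the novice is never counted). Respondents present at no
#' initiation have rate 0 regardless of the (never asked) others count.
#' Initiators whose others-present answer is missing get `NA` — they are
#' "unusable" and the caller decides the exclusion.
#'
#' @param n_initiations_py Non-negative count(s) of past-year initiations the
#'   respondent was present at.
#' @param n_others_recent Count(s) of other injectors present at the most
#'   recent initiation (`NA` allowed; required to be `NA`-tolerant only when
#'   `n_initiations_py` is 0).
#' @return Numeric per-annum EFR rate(s).
#' @examples
#' respondent_efr(3, 2) # three-way equal share of 3 events
#' respondent_efr(5, 0) # sole responsible initiator
#' respondent_efr(0, NA)
#' @export
respondent_efr <- function(n_initiations_py, n_others_recent) {
  if (any(n_initiations_py < 0, na.rm = TRUE)) {
    abort("`n_initiations_py` must be non-negative.")
  }
  if (any(n_others_recent < 0, na.rm = TRUE)) {
    abort("`n_others_recent` must be non-negative (or NA).")
  }
  ifelse(n_initiations_py == 0, 0, n_initiations_py / (n_others_recent + 1))
}

# Restrict records to a subgroup key; NULL key fields mean "pooled over that
# factor". Records missing a *keyed* field are dropped.
filter_subgroup <- function(records, sex = NULL, region = NULL,
                            career_bin = NULL, prison = NULL,
                            past_year_only = FALSE) {
  out <- records
  if (!is.null(sex)) {
    stopifnot(sex %in% c("F", "M"))
    out <- filter(out, !is.na(.data$sex), .data$sex == !!sex)
  }
  if (!is.null(region)) {
    stopifnot(region %in% c("GGC", "Else"))
    out <- filter(out, !is.na(.data$region), .data$region == !!region)
  }
  if (!is.null(career_bin)) {
    stopifnot(career_bin %in% CAREER_BINS)
    out <- filter(out, career_bin(.data$career_years) == !!career_bin)
  }
  if (!is.null(prison)) {
    stopifnot(prison %in% c("never", "ever"))
    out <- filter(out, .data$ever_incarcerated == (!!prison == "ever"))
  }
  if (past_year_only) {
    out <- filter(out, !is.na(.data$injected_past_year), .data$injected_past_year)
  }
  out
}

#' Subgroup EFR estimate
#'
#' Point summary of a survey subgroup: respondent and initiator counts, total
#' initiations, mean initiations per respondent per annum, mean number of
#' other injectors present (averaged over initiators only), and the subgroup
#' EFR rate `lambda_efr` — the mean of per-respondent EFR rates with zeros
#' included. Initiators with a missing others-present answer cannot contribute
#' a responsibility share and are excluded from both numerators and the
#' denominator; their number is reported in `n_dropped_missing`.
#'
#' Key arguments left `NULL` are pooled over. `past_year_only = TRUE`
#' restricts to respondents who injected in the past year (the sensitivity
#' analysis that treats non-past-year injectors' responsibility as 0 by
#' excluding them).
#'
#' @param records A respondent tibble (see [read_cohort()] for the columns).
#' @param sex,region,career_bin,prison Optional subgroup key values
#'   (`"F"/"M"`, `"GGC"/"Else"`, `"0-5"/"6-10"/">=11"`, `"never"/"ever"`).
#' @param past_year_only Restrict to past-year injectors?
#' @return A one-row tibble with the key columns (NA = pooled) and the summary
#'   fields.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_respondents = 1000, seed = 3))
#' efr_estimate(cohort$records)
#' efr_estimate(cohort$records, sex = "M", prison = "never")
#' @export
efr_estimate <- function(records, sex = NULL, region = NULL, career_bin = NULL,
                         prison = NULL, past_year_only = FALSE) {
  sub <- filter_subgroup(records, sex, region, career_bin, prison, past_year_only)
  if (nrow(sub) == 0) {
    abort("Empty subgroup: no records match the requested key.")
  }
  unusable <- sub$n_initiations_py > 0 & is.na(sub$n_others_recent)
  kept <- sub[!unusable, , drop = FALSE]
  if (nrow(kept) == 0) {
    abort("Empty subgroup after excluding initiators with missing others-present counts.")
  }
  efr <- respondent_efr(kept$n_initiations_py, kept$n_others_recent)
  init <- kept$n_initiations_py > 0
  tibble(
    sex = sex %||% NA_character_,
    region = region %||% NA_character_,
    career_bin = career_bin %||% NA_character_,
    prison = prison %||% NA_character_,
    n_respondents = nrow(kept),
    n_initiators = sum(init),
    n_initiations = sum(kept$n_initiations_py),
    mean_initiations_pa = sum(kept$n_initiations_py) / nrow(kept),
    mean_others_present = if (any(init)) mean(kept$n_others_recent[init]) else NA_real_,
    lambda_efr = mean(efr),
    n_dropped_missing = sum(unusable)
  )
}

#' Paired bootstrap for a subgroup EFR rate
#'
#' Nonparametric bootstrap of the subgroup EFR rate: respondents are resampled
#' with replacement within the subgroup, each carrying its (initiations,
#' others-present) pair jointly, and `lambda_efr` is recomputed per replicate.
#' The confidence interval is the percentile interval, and `log_lambda_var` is
#' the sample variance of `log(lambda)` over the replicates with positive
#' lambda — the precision weight used by [efr_regression()]. Zero-lambda
#' replicates are counted in `n_zero_replicates`; a subgroup whose replicates
#' are all zero has an undefined interval and is flagged with a warning and
#' `NA` bounds.
#'
#' @inheritParams efr_estimate
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level.
#' @param seed Integer seed; results are reproducible given the seed.
#' @return A one-row tibble: the [efr_estimate()] fields plus `ci_low`,
#'   `ci_high`, `log_lambda_var`, `n_zero_replicates`, `n_boot`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_respondents = 500, seed = 3))
#' efr_bootstrap(cohort$records, prison = "ever", n_boot = 200, seed = 11)
#' @export
efr_bootstrap <- function(records, sex = NULL, region = NULL, career_bin = NULL,
                          prison = NULL, past_year_only = FALSE,
                          n_boot = 5000, level = 0.95, seed) {
  if (missing(seed)) abort("`seed` must be given explicitly.")
  point <- efr_estimate(records, sex, region, career_bin, prison, past_year_only)

  sub <- filter_subgroup(records, sex, region, career_bin, prison, past_year_only)
  sub <- sub[!(sub$n_initiations_py > 0 & is.na(sub$n_others_recent)), , drop = FALSE]
  efr <- respondent_efr(sub$n_initiations_py, sub$n_others_recent)
  n <- length(efr)

  reps <- withr::with_seed(seed, {
    vapply(seq_len(n_boot),
           function(b) mean(efr[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })

  alpha <- (1 - level) / 2
  pos <- reps > 0
  if (!any(pos)) {
    warn("All bootstrap replicates are zero; CI undefined for this subgroup.")
    ci <- c(NA_real_, NA_real_)
    lv <- NA_real_
  } else {
    ci <- unname(quantile(reps, c(alpha, 1 - alpha)))
    lv <- if (sum(pos) > 1) var(log(reps[pos])) else 0
  }
  mutate(point,
         ci_low = ci[1], ci_high = ci[2],
         log_lambda_var = lv,
         n_zero_replicates = sum(!pos),
         n_boot = n_boot)
}

# the standard report keys: All, prison margins, sex x prison, region x prison,
# career x prison (17 rows), or the 12 sex x career x prison regression cells
standard_keys <- function(which = c("report", "regression")) {
  which <- match.arg(which)
  if (which == "regression") {
    return(tidyr::crossing(sex = c("F", "M"), career_bin = CAREER_BINS,
                           prison = c("never", "ever")) %>%
             mutate(region = NA_character_) %>%
             select("sex", "region", "career_bin", "prison"))
  }
  bind_rows(
    tibble(sex = NA, region = NA, career_bin = NA, prison = NA_character_),
    tidyr::crossing(prison = c("never", "ever")) %>%
      mutate(sex = NA, region = NA, career_bin = NA),
    tidyr::crossing(sex = c("M", "F"), prison = c("never", "ever")) %>%
      mutate(region = NA, career_bin = NA),
    tidyr::crossing(region = c("GGC", "Else"), prison = c("never", "ever")) %>%
      mutate(sex = NA, career_bin = NA),
    tidyr::crossing(career_bin = CAREER_BINS, prison = c("never", "ever")) %>%
      mutate(sex = NA, region = NA)
  ) %>%
    select("sex", "region", "career_bin", "prison")
}

#' Subgroup EFR report table
#'
#' Computes [efr_bootstrap()] rows for a set of subgroup keys. The default
#' `keys = "report"` produces the standard 17-row survey report (overall,
#' by prison history, and prison history crossed with sex, region and career
#' bin); `keys = "regression"` produces the 12 sex x career-bin x prison cells
#' consumed by [efr_regression()]. A custom tibble of keys (columns `sex`,
#' `region`, `career_bin`, `prison`; `NA` = pooled) may also be given.
#'
#' @inheritParams efr_bootstrap
#' @param keys `"report"`, `"regression"`, or a tibble of keys.
#' @return A tibble of class `efr_table`, one row per key.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_respondents = 800, seed = 5))
#' efr_table(cohort$records, keys = "regression", n_boot = 100, seed = 2)
#' @export
efr_table <- function(records, keys = "report", past_year_only = FALSE,
                      n_boot = 5000, level = 0.95, seed) {
  if (missing(seed)) abort("`seed` must be given explicitly.")
  if (is.character(keys)) keys <- standard_keys(keys)
  key_seeds <- seed + seq_len(nrow(keys)) - 1L
  rows <- purrr::pmap(
    list(keys$sex, keys$region, keys$career_bin, keys$prison, key_seeds),
    function(s, r, cb, pr, sd) {
      efr_bootstrap(records,
                    sex = if (is.na(s)) NULL else s,
                    region = if (is.na(r)) NULL else r,
                    career_bin = if (is.na(cb)) NULL else as.character(cb),
                    prison = if (is.na(pr)) NULL else pr,
                    past_year_only = past_year_only,
                    n_boot = n_boot, level = level, seed = sd)
    }
  )
  out <- bind_rows(rows)
  class(out) <- c("efr_table", class(out))
  out
}

#' Descriptive initiator counts
#'
#' Who initiates: counts and proportions of past-year initiators overall, by
#' past-year injection status and by career length (0-5 vs longer), plus the
#' fraction of (usable) initiators reporting that no other injector was
#' present, split by incarceration history.
#'
#' @inheritParams efr_estimate
#' @return A tibble with columns `statistic`, `numerator`, `denominator`,
#'   `proportion`. An empty input gives an all-zero table.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_respondents = 500, seed = 9))
#' descriptive_counts(cohort$records)
#' @export
descriptive_counts <- function(records) {
  init <- records$n_initiations_py > 0
  usable <- init & !is.na(records$n_others_recent)
  never <- !records$ever_incarcerated
  row <- function(statistic, num, den) {
    tibble(statistic = statistic, numerator = num, denominator = den,
           proportion = if (den > 0) num / den else 0)
  }
  bind_rows(
    row("initiators", sum(init), nrow(records)),
    row("initiators_past_year_injectors",
        sum(init & records$injected_past_year),
        sum(records$injected_past_year)),
    row("initiators_not_past_year_injectors",
        sum(init & !records$injected_past_year),
        sum(!records$injected_past_year)),
    row("initiators_career_0_5",
        sum(init & records$career_years <= 5),
        sum(records$career_years <= 5)),
    row("initiators_career_over_5",
        sum(init & records$career_years > 5),
        sum(records$career_years > 5)),
    row("zero_others_never_incarcerated",
        sum(usable & never & records$n_others_recent == 0),
        sum(usable & never)),
    row("zero_others_ever_incarcerated",
        sum(usable & !never & records$n_others_recent == 0),
        sum(usable & !never))
  )
}
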