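test_that("per-respondent EFR rate shares responsibility equally", {
  expect_equal(respondent_efr(3, 2), 1.0) # equal three-way share
  expect_equal(respondent_efr(5, 0), 5.0) # sole responsible initiator
  expect_equal(respondent_efr(0, NA), 0.0)
  expect_true(is.na(respondent_efr(2, NA))) # unusable initiator, caller excludes
  expect_error(respondent_efr(-1, 2), "non-negative")
})

test_that("subgroup estimates aggregate counts and handle missing initiators", {
  two <- make_records(n_init = c(4L, 0L), others = c(1L, NA))
  est <- efr_estimate(two)
  expect_equal(est$mean_initiations_pa, 2.0)
  expect_equal(est$lambda_efr, 1.0)

  # an initiator with missing others is dropped from numerators and denominator
  three <- make_records(n_init = c(4L, 0L, 7L), others = c(1L, NA, NA))
  est3 <- efr_estimate(three)
  expect_equal(est3$n_respondents, 2L)
  expect_equal(est3$n_initiations, 4L)
  expect_equal(est3$n_dropped_missing, 1L)
  expect_equal(est3$lambda_efr, 1.0)

  expect_error(efr_estimate(two, sex = "F"), "Empty subgroup")
})

test_that("lambda is invariant to record order and dataset duplication, and pools consistently", {
  coh <- generate_cohort(cohort_config(n_respondents = 2000, seed = 13))
  rec <- coh$records
  lam <- efr_estimate(rec)$lambda_efr
  shuffled <- rec[withr::with_seed(1, sample(nrow(rec))), ]
  expect_equal(efr_estimate(shuffled)$lambda_efr, lam)
  expect_equal(efr_estimate(dplyr::bind_rows(rec, rec))$lambda_efr, lam)

  all_row <- efr_estimate(rec)
  never <- efr_estimate(rec, prison = "never")
  ever <- efr_estimate(rec, prison = "ever")
  expect_equal(never$n_initiations + ever$n_initiations, all_row$n_initiations)
  expect_equal(never$n_respondents + ever$n_respondents, all_row$n_respondents)
})

test_that("equal-share responsibility equals the expected randomly-assigned full share", {
  # if one of the k+1 injectors present is given full responsibility uniformly
  # at random, the focal injector's expected share is 1/(k+1)
  for (k in c(1L, 3L)) {
    draws <- withr::with_seed(100 + k, sample.int(k + 1, 1e5, replace = TRUE) == 1L)
    mc <- mean(draws)
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mc - respondent_efr(1, k)), 3 * se)
  }
})

test_that("degenerate subgroups give degenerate bootstrap intervals", {
  same <- make_records(n_init = rep(3L, 20), others = rep(2L, 20))
  bs <- efr_bootstrap(same, n_boot = 200, seed = 9)
  expect_equal(bs$ci_low, 1.0)
  expect_equal(bs$ci_high, 1.0)
  expect_equal(bs$log_lambda_var, 0)
  expect_equal(bs$n_zero_replicates, 0L)

  zeros <- make_records(n_init = rep(0L, 5), others = rep(NA_integer_, 5))
  expect_warning(bs0 <- efr_bootstrap(zeros, n_boot = 50, seed = 2), "zero")
  expect_true(is.na(bs0$ci_low))
})

test_that("two-respondent bootstrap matches the exhaustive enumeration oracle", {
  # resamples of {(2,1), (0,-)} are {AA, AB, BA, BB}, equally likely, with
  # replicate lambda {1, 0.5, 0.5, 0}: mean 0.5, P(0) = P(1) = 1/4
  two <- make_records(n_init = c(2L, 0L), others = c(1L, NA))
  n_boot <- 4000
  bs <- efr_bootstrap(two, n_boot = n_boot, seed = 42)
  sub <- two
  reps <- withr::with_seed(42, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(2, 2, replace = TRUE)
    mean(respondent_efr(sub$n_initiations_py[idx], sub$n_others_recent[idx]))
  }, numeric(1)))
  expect_setequal(unique(reps), c(0, 0.5, 1))
  sd_rep <- sqrt(1 / 8) # sd of the enumeration distribution
  expect_lt(abs(mean(reps) - 0.5), 3 * sd_rep / sqrt(n_boot))
  expect_lt(abs(mean(reps == 0) - 0.25), 3 * sqrt(0.25 * 0.75 / n_boot))
  expect_equal(bs$n_zero_replicates, sum(reps == 0))
  # determinism given the seed
  expect_identical(bs, efr_bootstrap(two, n_boot = n_boot, seed = 42))
})

test_that("bootstrap interval width shrinks with subgroup size", {
  coh <- generate_cohort(cohort_config(n_respondents = 8000, seed = 21))
  rec <- coh$records
  width <- function(n) {
    bs <- efr_bootstrap(rec[seq_len(n), ], n_boot = 400, seed = 3)
    bs$ci_high - bs$ci_low
  }
  expect_lt(width(8000), width(800))
})

test_that("descriptive counts reproduce published fractions and handle empty input", {
  rec <- dplyr::bind_rows(
    records_from_counts(806, 187, 400, career = 3L),
    records_from_counts(1730, 266, 700, career = 8L)
  )
  counts <- descriptive_counts(rec)
  overall <- counts[counts$statistic == "initiators", ]
  expect_equal(overall$numerator, 453)
  expect_equal(overall$denominator, 2536)
  expect_equal(round(100 * overall$proportion), 18)
  early <- counts[counts$statistic == "initiators_career_0_5", ]
  expect_equal(round(100 * early$proportion), 23)

  empty <- descriptive_counts(make_records(integer(0), integer(0)))
  expect_true(all(empty$numerator == 0))
  expect_true(all(empty$proportion == 0))
})

test_that("the past-year-only switch excludes non-past-year injectors", {
  rec <- make_records(n_init = c(2L, 0L, 4L), others = c(1L, NA, 1L),
                      past_year = c(TRUE, TRUE, FALSE))
  full <- efr_estimate(rec)
  sens <- efr_estimate(rec, past_year_only = TRUE)
  expect_equal(full$n_respondents, 3L)
  expect_equal(sens$n_respondents, 2L)
  expect_equal(sens$n_initiations, 2L)
})

test_that("generated subgroup estimates cover their generating rates", {
  # the 12 sex x career x prison cells should trap their true lambda in the
  # bootstrap interval at roughly the nominal rate
  hits <- 0L; cells <- 0L
  for (s in 1:5) {
    coh <- generate_cohort(cohort_config(n_respondents = 50000, seed = 400 + s))
    est <- efr_table(coh$records, keys = "regression", n_boot = 300, seed = s)
    truth <- dplyr::mutate(coh$truth$cells, career_bin = as.character(career_bin))
    joined <- dplyr::left_join(
      est, truth,
      by = c("sex", "career_bin", "prison")
    )
    hits <- hits + sum(joined$ci_low <= joined$expected_lambda_est &
                         joined$expected_lambda_est <= joined$ci_high)
    cells <- cells + nrow(joined)
  }
  expect_gte(hits / cells, 0.90)
})
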