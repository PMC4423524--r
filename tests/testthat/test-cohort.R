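test_that("config validation names the offending field", {
  expect_error(cohort_config(n_respondents = 0), "n_respondents")
  expect_error(cohort_config(prop_female = 1.5), "prop_female")
  expect_error(cohort_config(career_cap_years = 10), "career_cap_years")
  expect_error(cohort_config(others_present_mean = -1), "others_present_mean")
  maps <- default_initiation_maps()
  expect_error(cohort_config(initiator_prob = maps$prob[-1, ]), "initiator_prob")
  bad_mean <- maps$mean
  bad_mean$mean_count[1] <- 0.5
  expect_error(cohort_config(initiation_count_mean = bad_mean), "initiation_count_mean")
})

test_that("zero initiator probability yields an initiation-free cohort", {
  maps <- default_initiation_maps()
  maps$prob$prob <- 0
  coh <- generate_cohort(cohort_config(n_respondents = 400,
                                       initiator_prob = maps$prob, seed = 2))
  expect_true(all(coh$records$n_initiations_py == 0))
  expect_true(all(is.na(coh$records$n_others_recent)))
})

test_that("identical configs reproduce identical cohorts and byte-identical files", {
  cfg <- cohort_config(n_respondents = 300, seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$records, b$records)
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_cohort(a, fa); write_cohort(b, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
})

test_that("a constant incarceration rate reproduces the geometric ever-incarcerated fraction", {
  p <- 0.08
  cfg <- cohort_config(
    n_respondents = 40000, seed = 31,
    incarceration_rates_by_sex = list(F = rep(p, 3), M = rep(p, 3)),
    missing_covariate_rate = 0
  )
  rec <- generate_cohort(cfg)$records
  for (t in c(2L, 6L, 13L)) {
    ever <- rec$ever_incarcerated[rec$career_years == t]
    expected <- 1 - (1 - p)^t
    se <- sqrt(expected * (1 - expected) / length(ever))
    expect_lt(abs(mean(ever) - expected), 3 * se + 1e-12)
  }
})

test_that("subgroup initiation behaviour matches the analytic generating expectations", {
  coh <- generate_cohort(cohort_config(n_respondents = 50000, seed = 7))
  rec <- coh$records %>%
    dplyr::filter(!is.na(sex)) %>%
    dplyr::mutate(career_bin = career_bin(career_years),
                  prison = ifelse(ever_incarcerated, "ever", "never"))
  obs <- rec %>%
    dplyr::group_by(sex, career_bin, prison) %>%
    dplyr::summarise(mean_init = mean(n_initiations_py),
                     se = sd(n_initiations_py) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop") %>%
    dplyr::left_join(coh$truth$cells,
                     by = c("sex", "career_bin", "prison"))
  expect_true(all(obs$n > 100))
  expect_true(all(abs(obs$mean_init - obs$expected_mean_initiations) <= 3 * obs$se))

  # overall initiator fraction and mean others-present sit near their targets
  expect_lt(abs(mean(rec$n_initiations_py > 0) - 0.18), 0.02)
  others <- rec$n_others_recent[!is.na(rec$n_others_recent)]
  expect_lt(abs(mean(others) - 2.5), 3 * sd(others) / sqrt(length(others)))
})

test_that("round trip preserves records including missing markers", {
  coh <- generate_cohort(cohort_config(n_respondents = 250, seed = 5))
  expect_gt(sum(is.na(coh$records$sex) | is.na(coh$records$region) |
                  is.na(coh$records$age_group)), 0)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, f)
  expect_identical(read_cohort(f), coh$records)

  one <- make_records(n_init = c(3L, 0L), others = c(NA_integer_, NA_integer_))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(one, f2) # initiator with missing others survives the trip
  expect_identical(read_cohort(f2), one)
})

test_that("an empty cohort writes a header-only file that reads back empty", {
  empty <- make_records(integer(0), integer(0))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(empty, f)
  expect_length(readLines(f), 1L)
  back <- read_cohort(f)
  expect_equal(nrow(back), 0L)
  expect_identical(names(back), names(empty))
})

test_that("malformed tables are rejected with the offending row", {
  bad <- make_records(n_init = 1L, others = 0L)
  bad$career_years <- -1L
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, f, na = "")
  expect_error(read_cohort(f), "career_years.*rows 1")

  bad2 <- make_records(n_init = 1L, others = 0L, sex = "X")
  f2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad2, f2, na = "")
  expect_error(read_cohort(f2), "sex")

  bad3 <- make_records(n_init = 0L, others = NA_integer_)
  bad3$n_others_recent <- 4L # others answered by a non-initiator
  f3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad3, f3, na = "")
  expect_error(read_cohort(f3), "n_others_recent")
})
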