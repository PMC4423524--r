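test_that("career survival and expected career length follow the geometric model", {
  expect_equal(career_survival(0, 0.3, 0.1), 0.9)
  expect_equal(career_survival(3, 0.5, 0), 0.125)
  # E[IC] = sum_{t>=0} P(IC > t) = (1 - q)/c
  expect_equal(sum(career_survival(0:5000, 0.05, 0.05)), 19.0, tolerance = 1e-8)
  expect_error(career_survival(-1, 0.1, 0.1), "whole years")
})

test_that("the EFR lookup switches from never to ever rates at first incarceration", {
  tab <- nesi_efr_lookup()
  expect_equal(efr_lookup(3, x = 2, tab), 0.26)
  expect_equal(efr_lookup(3, x = 7, tab), 0.46)
  expect_equal(efr_lookup(11, x = Inf, tab), 0.11)
  expect_equal(efr_lookup(7, x = 7, tab), 0.22) # incarcerated in year t counts as ever
  expect_error(efr_lookup(3, x = 2, tab, stratum = "nope"), "Unknown stratum")
  expect_error(efr_lookup_table(c(-1, 0, 0), c(0, 0, 0)), "non-negative")
})

test_that("constant EFR rates collapse R to lambda (1-q)/c exactly", {
  tab <- efr_lookup_table(rep(0.3, 3), rep(0.3, 3))
  for (cq in list(c(0.05, 0.05), c(0.2, 0.1), c(0.6, 0))) {
    r <- replacement_rate(tab, c(0.14, 0.05, 0.04), cessation = cq[1], quit = cq[2])
    expect_equal(r$R, 0.3 * (1 - cq[2]) / cq[1], tolerance = 1e-10)
  }
})

test_that("edge cases: full quitting, divergence, and term bookkeeping", {
  tab <- nesi_efr_lookup()
  r <- replacement_rate(tab, nesi_incarceration_rates(), cessation = 0.1, quit = 1)
  expect_equal(r$R, 0)
  expect_gt(r$f_value, 0) # f is defined independently of q
  expect_error(replacement_rate(tab, nesi_incarceration_rates(), cessation = 0),
               "diverges")
  r2 <- replacement_rate(tab, nesi_incarceration_rates(), cessation = 0.05)
  expect_equal(sum(r2$per_year_terms$value), r2$R, tolerance = 1e-12)
  expect_equal(r2$R, (1 - r2$quit) * r2$f_value, tolerance = 1e-12)
})

test_that("all three evaluation routes agree to floating-point accuracy", {
  withr::with_seed(14, {
    for (rep in 1:8) {
      tab <- efr_lookup_table(runif(3, 0, 0.6), runif(3, 0, 0.6))
      p <- runif(3, 0.01, 0.5)
      cess <- runif(1, 0.03, 0.6)
      quit <- runif(1, 0, 0.9)
      closed <- replacement_rate(tab, p, cess, quit)$R
      series <- replacement_rate(tab, p, cess, quit, method = "series", tol = 1e-14)$R
      pmf <- replacement_rate(tab, p, cess, quit, method = "pmf_sum", tol = 1e-14)$R
      expect_equal(series, closed, tolerance = 1e-10)
      expect_equal(pmf, closed, tolerance = 1e-10)
    }
  })
})

test_that("R is monotone in cessation, quit and every EFR rate, and proportional to 1-q", {
  p <- nesi_incarceration_rates()
  base_tab <- nesi_efr_lookup()
  base <- replacement_rate(base_tab, p, 0.1, 0.1)$R
  expect_lt(replacement_rate(base_tab, p, 0.1 + 0.02, 0.1)$R, base)
  expect_lt(replacement_rate(base_tab, p, 0.1, 0.1 + 0.02)$R, base)
  for (i in 1:3) {
    ln <- base_tab$lambda_never; le <- base_tab$lambda_ever
    ln[i] <- ln[i] + 0.05
    expect_gt(replacement_rate(efr_lookup_table(ln, base_tab$lambda_ever), p, 0.1, 0.1)$R, base)
    le[i] <- le[i] + 0.05
    expect_gt(replacement_rate(efr_lookup_table(base_tab$lambda_never, le), p, 0.1, 0.1)$R, base)
  }
  # exact proportionality to (1 - q)
  r0 <- replacement_rate(base_tab, p, 0.1, quit = 0)$R
  for (q in c(0.2, 0.5, 0.9)) {
    expect_equal(replacement_rate(base_tab, p, 0.1, quit = q)$R, (1 - q) * r0,
                 tolerance = 1e-12)
  }
})

test_that("multi-stratum tables combine with respondent weights", {
  tab <- dplyr::bind_rows(
    efr_lookup_table(c(0.4, 0.2, 0.1), c(0.3, 0.2, 0.2), stratum = "F"),
    efr_lookup_table(c(0.5, 0.3, 0.1), c(0.2, 0.2, 0.2), stratum = "M")
  )
  rates <- list(F = c(0.07, 0.06, 0.04), M = c(0.19, 0.05, 0.03))
  rf <- replacement_rate(tab, rates$F, 0.1, stratum = "F")$R
  rm <- replacement_rate(tab, rates$M, 0.1, stratum = "M")$R
  both <- replacement_rate(tab, rates, 0.1, stratum_weights = c(F = 0.28, M = 0.72))
  expect_equal(both$R, 0.28 * rf + 0.72 * rm, tolerance = 1e-12)
  expect_error(replacement_rate(tab, rates, 0.1), "stratum_weights")
})

test_that("the unit-replacement quit rate inverts the model", {
  q <- quit_rate_for_unit_replacement(4.8, 0.05)
  expect_equal(round(q$q_prime, 2), 0.80)
  expect_false(q$below_replacement)
  expect_equal(quit_rate_for_unit_replacement(1 - 0.1, 0.1)$q_prime, 0)
  low <- quit_rate_for_unit_replacement(0.5, 0.1)
  expect_true(low$below_replacement)
  expect_lt(low$q_prime, 0)
  expect_error(quit_rate_for_unit_replacement(-2, 0.1), "positive")

  # plugging q' back into the model returns R = 1
  tab <- nesi_efr_lookup()
  for (cess in c(0.05, 0.10, 0.15)) {
    r <- replacement_rate(tab, nesi_incarceration_rates(), cess)
    qp <- quit_rate_for_unit_replacement(r$R, cess)$q_prime
    r1 <- replacement_rate(tab, nesi_incarceration_rates(), cess, quit = qp)
    expect_equal(r1$R, 1, tolerance = 1e-9)
  }
})

test_that("replacement agrees with the Monte-Carlo career-simulation oracle", {
  tab <- nesi_efr_lookup()
  p <- nesi_incarceration_rates()
  r <- replacement_rate(tab, p, cessation = 0.1, quit = 0.1)$R
  mc <- mc_replacement_oracle(tab$lambda_never, tab$lambda_ever, p,
                              cess = 0.1, quit = 0.1, n_careers = 2e5, seed = 99)
  expect_lt(abs(mc$mean - r), 3 * mc$se)
})

test_that("joint bootstrap of R behaves on degenerate and tiny inputs", {
  same <- make_records(n_init = rep(2L, 30), others = rep(1L, 30),
                       career = 3L, ever = FALSE)
  ci <- replacement_ci(same, cessation = 0.1, n_boot = 20, seed = 4)
  expect_equal(unname(ci$ci["low"]), unname(ci$ci["high"]))
  expect_equal(ci$n_failed, 0L)

  one_rep <- replacement_ci(same, cessation = 0.1, n_boot = 1, seed = 4)
  expect_equal(unname(one_rep$ci["low"]), unname(one_rep$ci["high"]))
  expect_equal(unname(one_rep$ci["low"]), one_rep$replicates[1])

  # deterministic given the seed
  coh <- generate_cohort(cohort_config(n_respondents = 600, seed = 44))
  a <- replacement_ci(coh$records, cessation = 0.1, n_boot = 25, seed = 5)
  b <- replacement_ci(coh$records, cessation = 0.1, n_boot = 25, seed = 5)
  expect_identical(a$replicates, b$replicates)
})

test_that("bootstrap intervals for R cover the generating analytic value", {
  # analytic R of the generating process, from the truth cells and true rates
  hits <- 0L
  n_seeds <- 12L
  for (s in seq_len(n_seeds)) {
    cfg <- cohort_config(n_respondents = 1500, seed = 800 + s,
                         prop_female = 0, missing_covariate_rate = 0)
    coh <- generate_cohort(cfg)
    truth <- dplyr::filter(coh$truth$cells, sex == "M")
    tab <- efr_lookup_from_estimates(
      dplyr::rename(truth, lambda_efr = expected_lambda_est)
    )
    r_true <- replacement_rate(tab, cfg$incarceration_rates_by_sex$M,
                               cessation = 0.05, quit = 0.05)$R
    ci <- replacement_ci(coh$records, cessation = 0.05, n_boot = 120, seed = s)
    hits <- hits + (ci$ci["low"] <= r_true && r_true <= ci$ci["high"])
  }
  expect_gte(hits, ceiling(0.8 * n_seeds)) # ~95% nominal; generous binomial slack at 12 draws
})
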