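# Fixture builders and independent oracles used across the suite.

# Quick respondent-table constructor; scalar arguments are recycled.
make_records <- function(n_init, others, sex = "M", region = "GGC",
                         age = "<35", career = 3L, ever = FALSE,
                         past_year = TRUE) {
  n <- length(n_init)
  tibble::tibble(
    id = sprintf("T%06d", seq_len(n)),
    sex = rep_len(sex, n),
    region = rep_len(region, n),
    age_group = rep_len(age, n),
    career_years = as.integer(rep_len(career, n)),
    ever_incarcerated = rep_len(ever, n),
    injected_past_year = rep_len(past_year, n),
    n_initiations_py = as.integer(n_init),
    n_others_recent = as.integer(others)
  )
}

# Records reproducing printed marginal counts: `n_initiators` initiators whose
# past-year counts sum to `total_initiations` (spread as evenly as possible),
# the rest non-initiators.
records_from_counts <- function(n_respondents, n_initiators, total_initiations,
                                others = 2L, ...) {
  base <- total_initiations %/% n_initiators
  rem <- total_initiations %% n_initiators
  counts <- rep(base, n_initiators) + c(rep(1L, rem), rep(0L, n_initiators - rem))
  stopifnot(all(counts >= 1), sum(counts) == total_initiations)
  make_records(
    n_init = c(counts, rep(0L, n_respondents - n_initiators)),
    others = c(rep(others, n_initiators), rep(NA_integer_, n_respondents - n_initiators)),
    ...
  )
}

# Direct weighted normal-equation solve: beta = (X'WX)^{-1} X'Wy, SEs from the
# weighted residual variance on n - p df.
wls_oracle <- function(y, X, w) {
  XtWX <- t(X) %*% (w * X)
  beta <- solve(XtWX, t(X) %*% (w * y))
  resid <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(w * resid^2) / df
  se <- sqrt(diag(solve(XtWX)) * sigma2)
  tstat <- beta[, 1] / se
  list(coef = beta[, 1], se = se,
       p = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE))
}

# Per-record log-likelihood evaluated directly from the piecewise survival
# formula (no binning) — shared by the grid-search oracles below.
naive_loglik <- function(records, p) {
  t <- records$career_years
  ls <- ifelse(t <= 5, t * log1p(-p[1]),
        ifelse(t <= 10, 5 * log1p(-p[1]) + (t - 5) * log1p(-p[2]),
               5 * log1p(-p[1]) + 5 * log1p(-p[2]) + (t - 10) * log1p(-p[3])))
  s <- ifelse(t == 0, 1, exp(ls))
  sum(ifelse(records$ever_incarcerated, log(1 - s), log(s)))
}

# Dense 3-D grid search over the incarceration likelihood, with local
# refinement rounds around the running best.
grid_fit_oracle <- function(records, n_grid = 21, refine = 3) {
  ll <- function(p1, p2, p3) naive_loglik(records, c(p1, p2, p3))
  lo <- rep(1e-6, 3); hi <- rep(1 - 1e-6, 3)
  best <- NULL
  for (round in seq_len(refine + 1)) {
    g1 <- seq(lo[1], hi[1], length.out = n_grid)
    g2 <- seq(lo[2], hi[2], length.out = n_grid)
    g3 <- seq(lo[3], hi[3], length.out = n_grid)
    grid <- expand.grid(p1 = g1, p2 = g2, p3 = g3)
    vals <- mapply(ll, grid$p1, grid$p2, grid$p3)
    best <- as.numeric(grid[which.max(vals), ])
    step <- c(g1[2] - g1[1], g2[2] - g2[1], g3[2] - g3[1])
    lo <- pmax(best - step, 1e-6)
    hi <- pmin(best + step, 1 - 1e-6)
  }
  best
}

# One-parameter geometric MLE by 1-D grid search (all careers within one piece).
grid_fit_1d_oracle <- function(records, tol = 1e-6) {
  ll <- function(p) naive_loglik(records, c(p, p, p))
  lo <- 1e-6; hi <- 1 - 1e-6
  while (hi - lo > tol / 2) {
    g <- seq(lo, hi, length.out = 41)
    v <- vapply(g, ll, numeric(1))
    i <- which.max(v)
    lo <- g[max(i - 1, 1)]; hi <- g[min(i + 1, length(g))]
  }
  (lo + hi) / 2
}

# Monte-Carlo career-simulation oracle for the replacement rate: simulate
# individual careers year by year (immediate quit, geometric cessation,
# piecewise first-incarceration drawn from a cumprod survival grid) and
# average the accrued EFR responsibility. Returns mean and MC standard error.
mc_replacement_oracle <- function(lambda_never, lambda_ever, p, cess, quit,
                                  n_careers, seed) {
  withr::with_seed(seed, {
    quits <- stats::runif(n_careers) < quit
    ic <- ifelse(quits, 0L, stats::rgeom(n_careers, cess) + 1L) # active years: t = 0..ic-1
    tmax <- max(ic)
    hazard_bin <- ifelse(seq_len(tmax) <= 5, 1L, ifelse(seq_len(tmax) <= 10, 2L, 3L))
    surv_grid <- cumprod(1 - p[hazard_bin]) # S(1..tmax)
    u <- stats::runif(n_careers)
    # X = k iff S(k) < u <= S(k-1); beyond the grid = never incarcerated while active
    x_first <- tmax - findInterval(u, rev(surv_grid)) + 1L
    accrual <- numeric(n_careers)
    for (t in 0:(tmax - 1)) {
      active <- ic > t
      if (!any(active)) break
      b <- if (t <= 5) 1L else if (t <= 10) 2L else 3L
      lam <- ifelse(x_first <= t, lambda_ever[b], lambda_never[b])
      accrual <- accrual + active * lam
    }
    list(mean = mean(accrual), se = stats::sd(accrual) / sqrt(n_careers))
  })
}
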