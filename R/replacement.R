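#' Injecting-career survival
#'
#' Career length `IC` (whole years of active injecting) is geometric with
#' per-annum cessation probability `cessation`, thinned by a one-time
#' immediate quit probability `quit` for novices who never become active:
#' `P(IC > t) = (1 - quit) (1 - cessation)^t` for `t = 0, 1, 2, ...`.
#' The expected career length is `(1 - quit) / cessation`.
#'
#' @param t Non-negative integer career years (vectorised).
#' @param cessation Per-annum cessation probability `c` in (0, 1].
#' @param quit Immediate quit probability `q` in \[0, 1\].
#' @return `P(IC > t)`.
#' @examples
#' career_survival(0, 0.05, 0.05) # 1 - q
#' career_survival(3, 0.5, 0)     # 0.125
#' @export
career_survival <- function(t, cessation, quit = cessation) {
  check_career_params(cessation, quit)
  if (any(is.na(t)) || any(t < 0) || any(t != floor(t))) {
    abort("`t` must be non-negative whole years.")
  }
  (1 - quit) * (1 - cessation)^t
}

check_career_params <- function(cessation, quit) {
  check_prob(cessation, "cessation")
  check_prob(quit, "quit")
  invisible(NULL)
}

#' EFR lookup table for the replacement-rate model
#'
#' The replacement-rate model needs the per-annum EFR initiation rate as a
#' function of career year `t` and first-incarceration year `x`:
#' `lambda_ever[bin(t)]` once incarceration has occurred (`x <= t`), else
#' `lambda_never[bin(t)]`, with the usual career bins (`t` in 0-5, 6-10,
#' >=11; `t` is 0-indexed, so bin 0-5 covers `t = 0, ..., 5`).
#'
#' @param lambda_never,lambda_ever Numeric triples of per-annum EFR rates for
#'   bins 0-5, 6-10, >=11.
#' @param stratum Stratum label (e.g. `"overall"`, `"F"`, `"M"`).
#' @return A tibble of class `efr_lookup_table` (columns `stratum`,
#'   `career_bin`, `lambda_never`, `lambda_ever`); rows for several strata can
#'   be combined with [dplyr::bind_rows()].
#' @examples
#' nesi_efr_lookup()
#' @export
efr_lookup_table <- function(lambda_never, lambda_ever, stratum = "overall") {
  for (v in list(lambda_never, lambda_ever)) {
    if (!is.numeric(v) || length(v) != 3L || any(is.na(v)) || any(v < 0)) {
      abort("`lambda_never` and `lambda_ever` must be non-negative numeric triples (bins 0-5, 6-10, >=11).")
    }
  }
  out <- tibble(
    stratum = stratum,
    career_bin = factor(CAREER_BINS, levels = CAREER_BINS),
    lambda_never = as.numeric(lambda_never),
    lambda_ever = as.numeric(lambda_ever)
  )
  class(out) <- c("efr_lookup_table", class(out))
  out
}

#' Build an EFR lookup table from subgroup estimates
#'
#' Converts career-bin x prison subgroup EFR estimates (for example the
#' relevant rows of an [efr_table()]) into an [efr_lookup_table()]. If a
#' `stratum_col` is given (e.g. `"sex"`), one stratum is built per value.
#'
#' @param estimates Tibble with columns `career_bin`, `prison`, `lambda_efr`
#'   (plus `stratum_col` if used), one row per cell.
#' @param stratum_col Optional column name to stratify by.
#' @return An `efr_lookup_table`.
#' @export
efr_lookup_from_estimates <- function(estimates, stratum_col = NULL) {
  build_one <- function(df, label) {
    lam <- function(pr) {
      vapply(CAREER_BINS, function(b) {
        v <- df$lambda_efr[df$career_bin == b & df$prison == pr]
        if (length(v) != 1L || is.na(v)) {
          abort(paste0("Missing lambda_efr for cell (", b, ", ", pr, ")",
                       if (!is.null(stratum_col)) paste0(" in stratum ", label) else "", "."))
        }
        v
      }, numeric(1))
    }
    efr_lookup_table(lam("never"), lam("ever"), stratum = label)
  }
  if (is.null(stratum_col)) return(build_one(estimates, "overall"))
  strata <- unique(estimates[[stratum_col]])
  out <- bind_rows(lapply(strata, function(s) {
    build_one(estimates[estimates[[stratum_col]] == s, , drop = FALSE], s)
  }))
  class(out) <- c("efr_lookup_table", class(out))
  out
}

#' @rdname efr_lookup_table
#' @param t Career year(s), non-negative integers.
#' @param x First-incarceration year (positive integer or `Inf` for never
#'   incarcerated).
#' @param table An `efr_lookup_table`.
#' @return `efr_lookup()` gives the per-annum EFR rate(s) `lambda(t, x)`.
#' @examples
#' efr_lookup(3, x = 2, nesi_efr_lookup())   # ever-incarcerated, bin 0-5
#' efr_lookup(3, x = 7, nesi_efr_lookup())   # not yet incarcerated at t = 3
#' @export
efr_lookup <- function(t, x, table, stratum = "overall") {
  if (any(t < 0) || any(t != floor(t))) abort("`t` must be non-negative whole years.")
  if (any(x[is.finite(x)] < 1) || any(x[is.finite(x)] != floor(x[is.finite(x)]))) {
    abort("`x` must be a positive whole year or Inf (never incarcerated).")
  }
  lam <- lookup_vectors(table, stratum)
  b <- ifelse(t <= 5, 1L, ifelse(t <= 10, 2L, 3L))
  ifelse(x <= t, lam$ever[b], lam$never[b])
}

lookup_vectors <- function(table, stratum) {
  rows <- table[table$stratum == stratum, , drop = FALSE]
  if (nrow(rows) != 3L) {
    abort(paste0("Unknown stratum `", stratum, "` in EFR lookup table."))
  }
  rows <- rows[match(CAREER_BINS, as.character(rows$career_bin)), ]
  list(never = rows$lambda_never, ever = rows$lambda_ever)
}

#' The injector replacement rate
#'
#' Expected number of EFR-weighted initiations over a full injecting career:
#' the discrete-time sum over career years `t` and first-incarceration years
#' `x` of `lambda(t, x) * P(IC > t) * P(X = x)`. `R = 1` corresponds to a
#' stable injector population, in analogy with an epidemic reproduction
#' number.
#'
#' The default evaluator exchanges the sums and works with the incarceration
#' survival function, `R = (1 - q) * sum_t (1-c)^t [ lambda_never(t) P(X > t)
#' + lambda_ever(t) (1 - P(X > t)) ]`, with the constant-rate tail from
#' `t >= 11` summed in closed form (two geometric series with ratios
#' `(1-c)` and `(1-c)(1-p3)`), so the result is exact to floating point.
#' `method = "series"` truncates the same sum at `tol`; `method = "pmf_sum"`
#' evaluates the original triple-sum ordering over `P(X = x)` (useful as a
#' cross-check). Because `q` enters only through `P(IC > t)`, `R` factors as
#' `R = (1 - q) f(p, c)`; `f` is returned as `f_value`.
#'
#' With a multi-stratum lookup table, per-stratum results are combined with
#' the supplied `stratum_weights` (e.g. survey proportions by sex), and
#' `rates` may be a named list of per-stratum incarceration triples.
#'
#' @param table An [efr_lookup_table()].
#' @param rates Incarceration rate triple `(p1, p2, p3)`, or a named list of
#'   triples keyed by stratum.
#' @param cessation Per-annum cessation probability `c` (must be > 0; the
#'   expected career is infinite at `c = 0`).
#' @param quit Immediate quit probability `q`; defaults to `cessation`.
#' @param stratum Evaluate a single stratum of a multi-stratum table.
#' @param stratum_weights Named weights (summing to 1) for combining strata.
#' @param method Evaluation route; see Details.
#' @param tol Truncation bound for the non-closed-form methods.
#' @return An object of class `replacement_result`: `R`, `f_value = R/(1-q)`,
#'   `per_year_terms` (addends for `t = 0..10` and the `>=11` tail),
#'   `truncation_error_bound`, and the inputs.
#' @examples
#' replacement_rate(nesi_efr_lookup(), nesi_incarceration_rates(), cessation = 0.05)
#' @export
replacement_rate <- function(table, rates, cessation, quit = cessation,
                             stratum = NULL, stratum_weights = NULL,
                             method = c("closed_form", "series", "pmf_sum"),
                             tol = 1e-12) {
  method <- match.arg(method)
  check_career_params(cessation, quit)
  if (cessation <= 0) {
    abort("`cessation` must be > 0: at c = 0 the expected career length (and R) diverges.")
  }
  strata <- unique(table$stratum)
  if (is.null(stratum) && length(strata) > 1L) {
    if (is.null(stratum_weights) || !all(strata %in% names(stratum_weights))) {
      abort("A multi-stratum table needs named `stratum_weights` covering every stratum.")
    }
    w <- stratum_weights[strata]
    if (abs(sum(w) - 1) > 1e-8) abort("`stratum_weights` must sum to 1.")
    parts <- lapply(strata, function(s) {
      replacement_rate(table, rates_for_stratum(rates, s), cessation, quit,
                       stratum = s, method = method, tol = tol)
    })
    names(parts) <- strata
    terms <- parts[[1]]$per_year_terms["career_year"]
    terms$value <- Reduce(`+`, purrr::map2(parts, w, ~ .x$per_year_terms$value * .y))
    out <- structure(
      list(
        R = sum(vapply(parts, `[[`, numeric(1), "R") * w),
        f_value = sum(vapply(parts, `[[`, numeric(1), "f_value") * w),
        per_year_terms = terms,
        truncation_error_bound = max(vapply(parts, `[[`, numeric(1), "truncation_error_bound")),
        cessation = cessation, quit = quit, stratum = "combined",
        components = parts, weights = w, method = method
      ),
      class = "replacement_result"
    )
    return(out)
  }
  stratum <- stratum %||% strata[1]
  lam <- lookup_vectors(table, stratum)
  p <- check_incarceration_rates(rates_for_stratum(rates, stratum))

  core <- switch(method,
    closed_form = repl_closed_form(lam$never, lam$ever, p, cessation),
    series = repl_series(lam$never, lam$ever, p, cessation, tol),
    pmf_sum = repl_pmf_sum(lam$never, lam$ever, p, cessation, tol)
  )
  structure(
    list(
      R = (1 - quit) * core$f,
      f_value = core$f,
      per_year_terms = tibble(career_year = core$labels,
                              value = (1 - quit) * core$terms),
      truncation_error_bound = (1 - quit) * core$bound,
      cessation = cessation, quit = quit, stratum = stratum, method = method
    ),
    class = "replacement_result"
  )
}

rates_for_stratum <- function(rates, stratum) {
  if (is.list(rates)) {
    if (!stratum %in% names(rates)) {
      abort(paste0("No incarceration rates supplied for stratum `", stratum, "`."))
    }
    rates[[stratum]]
  } else {
    rates
  }
}

# f(p, c) with the quit factor removed; exact closed-form geometric tail
repl_closed_form <- function(ln, le, p, cess) {
  beta <- 1 - cess
  t_head <- 0:10
  s <- incarceration_survival(t_head, p)
  b <- ifelse(t_head <= 5, 1L, 2L)
  head_terms <- beta^t_head * (ln[b] * s + le[b] * (1 - s))
  gamma <- 1 - p[3]
  s10 <- s[11] # P(X > 10)
  tail <- le[3] * beta^11 / cess +
    (ln[3] - le[3]) * s10 * beta^11 * gamma / (1 - beta * gamma)
  list(f = sum(head_terms) + tail,
       terms = c(head_terms, tail),
       labels = c(as.character(t_head), ">=11"),
       bound = 0)
}

repl_series <- function(ln, le, p, cess, tol) {
  beta <- 1 - cess
  lmax <- max(ln, le)
  f <- 0
  t <- 0L
  terms <- numeric(0)
  repeat {
    s <- incarceration_survival(t, p)
    b <- if (t <= 5) 1L else if (t <= 10) 2L else 3L
    term <- beta^t * (ln[b] * s + le[b] * (1 - s))
    f <- f + term
    terms <- c(terms, term)
    bound <- beta^(t + 1) * lmax / cess # remaining geometric mass
    if (bound < tol || t > 1e6) break
    t <- t + 1L
  }
  list(f = f, terms = terms, labels = as.character(0:t), bound = bound)
}

# the triple-sum ordering: outer sum over first-incarceration year x with
# P(X = x), inner sum over career years; X beyond the horizon acts as never
repl_pmf_sum <- function(ln, le, p, cess, tol) {
  beta <- 1 - cess
  lmax <- max(ln, le)
  # horizon T: career-year tail beyond T contributes < tol
  T <- 0L
  while (beta^(T + 1) * lmax / cess >= tol && T < 1e6) T <- T + 1L
  tt <- 0:T
  b <- ifelse(tt <= 5, 1L, ifelse(tt <= 10, 2L, 3L))
  disc <- beta^tt
  inner_never <- sum(disc * ln[b])
  f <- 0
  for (x in 1:(T + 1)) {
    lam_tx <- ifelse(x <= tt, le[b], ln[b])
    f <- f + incarceration_pmf(x, p) * sum(disc * lam_tx)
  }
  f <- f + incarceration_survival(T + 1, p) * inner_never
  list(f = f, terms = f, labels = "all", bound = beta^(T + 1) * lmax / cess)
}

#' @export
print.replacement_result <- function(x, ...) {
  cat("Injector replacement rate (stratum: ", x$stratum, ")\n", sep = "")
  cat("  R =", format(x$R, digits = 6),
      " at cessation c =", x$cessation, ", quit q =", x$quit, "\n")
  cat("  f(p, c) = R / (1 - q) =", format(x$f_value, digits = 6), "\n")
  invisible(x)
}

#' @describeIn replacement_rate Bar chart of the per-career-year addends of R.
#' @param object A `replacement_result`.
#' @param ... Unused.
#' @export
autoplot.replacement_result <- function(object, ...) {
  terms <- object$per_year_terms
  terms$career_year <- factor(terms$career_year, levels = terms$career_year)
  ggplot2::ggplot(terms, ggplot2::aes(x = .data$career_year, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "Career year",
      y = "Contribution to R (EFR initiations)",
      title = sprintf("Replacement rate R = %.2f (c = %.2f, q = %.2f)",
                      object$R, object$cessation, object$quit)
    ) +
    ggplot2::theme_minimal()
}

#' Quit rate required for one-for-one replacement
#'
#' Because `R(p, c, q) = (1 - q) f(p, c)`, the immediate quit rate that makes
#' the replacement rate exactly 1 follows in closed form from the replacement
#' rate evaluated at `q = c`: `q' = 1 - (1 - c) / R(p, c, c)`. A negative
#' `q'` means the population is already below one-for-one replacement at
#' `q = c`; it is reported unclamped with `below_replacement = TRUE`.
#'
#' @param R The replacement rate evaluated with `quit = cessation` (a number
#'   or a `replacement_result`).
#' @param cessation The per-annum cessation probability used for `R`.
#' @return A one-row tibble: `q_prime`, `below_replacement`.
#' @examples
#' quit_rate_for_unit_replacement(4.8, 0.05)
#' @export
quit_rate_for_unit_replacement <- function(R, cessation) {
  if (inherits(R, "replacement_result")) R <- R$R
  if (!is.numeric(R) || length(R) != 1L || is.na(R) || R <= 0) {
    abort("`R` must be a single positive replacement rate.")
  }
  if (!is.numeric(cessation) || cessation < 0 || cessation >= 1) {
    abort("`cessation` must lie in [0, 1).")
  }
  qp <- 1 - (1 - cessation) / R
  tibble(q_prime = qp, below_replacement = qp < 0)
}

#' Bootstrap confidence interval for the replacement rate
#'
#' Joint nonparametric bootstrap of the whole pipeline: respondents are
#' resampled with replacement; per replicate the career-bin x prison EFR
#' rates and (for `uncertainty = "joint"`, the default) the pooled
#' incarceration MLE are recomputed, and R is re-evaluated. The interval is
#' the percentile interval over replicates. Cells empty in the original data
#' contribute rate 0 throughout (they are structurally absent); a replicate
#' fails, and is skipped and counted, if a cell occupied in the original data
#' comes back empty. With `uncertainty = "efr_only"` the incarceration rates
#' are held at their full-data MLE.
#'
#' @inheritParams efr_estimate
#' @param cessation,quit Career parameters (see [career_survival()]).
#' @param n_boot Number of bootstrap replicates.
#' @param level Confidence level.
#' @param seed Integer seed; deterministic given the seed.
#' @param uncertainty `"joint"` or `"efr_only"`.
#' @return A list of class `replacement_ci`: `ci` (named low/high),
#'   `replicates`, `R_point`, `n_failed`, `n_boot`.
#' @export
replacement_ci <- function(records, cessation, quit = cessation,
                           n_boot = 500, level = 0.95, seed,
                           uncertainty = c("joint", "efr_only")) {
  if (missing(seed)) abort("`seed` must be given explicitly.")
  uncertainty <- match.arg(uncertainty)
  check_career_params(cessation, quit)

  prep <- records %>%
    mutate(
      usable = !(.data$n_initiations_py > 0 & is.na(.data$n_others_recent)),
      efr = respondent_efr(.data$n_initiations_py, .data$n_others_recent),
      bin = career_bin(.data$career_years),
      prison = factor(ifelse(.data$ever_incarcerated, "ever", "never"),
                      levels = c("never", "ever"))
    )
  cell_id <- interaction(prep$bin, prep$prison, drop = FALSE)
  occupied <- levels(cell_id)[tabulate(cell_id[prep$usable], nbins = nlevels(cell_id)) > 0]

  lambda_cells <- function(d_efr, d_cell, d_usable) {
    means <- tapply(d_efr[d_usable], d_cell[d_usable], mean)
    out <- setNames(rep(0, nlevels(cell_id)), levels(cell_id))
    out[names(means)[!is.na(means)]] <- means[!is.na(means)]
    if (any(is.na(match(occupied, names(means)))) ||
        any(is.na(means[occupied]))) return(NULL) # occupied cell came back empty
    out
  }
  to_lookup <- function(cells) {
    efr_lookup_table(
      lambda_never = cells[paste0(CAREER_BINS, ".never")],
      lambda_ever = cells[paste0(CAREER_BINS, ".ever")]
    )
  }
  fit_rates <- function(d) {
    cnt <- aggregate_incarceration(d)
    if (nrow(cnt) == 0) return(NULL)
    fit_incarceration_rates(cnt)
  }

  full_cells <- lambda_cells(prep$efr, cell_id, prep$usable)
  if (is.null(full_cells)) abort("No usable respondents to compute EFR cells.")
  full_rates <- fit_rates(prep)
  if (is.null(full_rates)) abort("No records with career_years > 0 to fit incarceration rates.")
  R_point <- replacement_rate(to_lookup(full_cells), full_rates, cessation, quit)$R

  n <- nrow(prep)
  reps <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      cells <- lambda_cells(prep$efr[idx], cell_id[idx], prep$usable[idx])
      if (is.null(cells)) return(NA_real_)
      rates <- if (uncertainty == "joint") {
        f <- fit_rates(prep[idx, , drop = FALSE])
        if (is.null(f)) return(NA_real_)
        f
      } else {
        full_rates
      }
      replacement_rate(to_lookup(cells), rates, cessation, quit)$R
    }, numeric(1))
  })

  n_failed <- sum(is.na(reps))
  if (n_failed > 0.05 * n_boot) {
    warn(sprintf("%d of %d bootstrap replicates failed (empty occupied cell).",
                 n_failed, n_boot))
  }
  ok <- reps[!is.na(reps)]
  alpha <- (1 - level) / 2
  structure(
    list(
      ci = setNames(unname(quantile(ok, c(alpha, 1 - alpha))), c("low", "high")),
      replicates = reps,
      R_point = R_point,
      n_failed = n_failed,
      n_boot = n_boot,
      level = level,
      cessation = cessation,
      quit = quit,
      uncertainty = uncertainty
    ),
    class = "replacement_ci"
  )
}

#' @export
print.replacement_ci <- function(x, ...) {
  cat("Replacement rate R =", format(x$R_point, digits = 4),
      sprintf(" (%.0f%% bootstrap CI: %.3g, %.3g)\n",
              100 * x$level, x$ci["low"], x$ci["high"]))
  cat("  c =", x$cessation, ", q =", x$quit, ",", x$n_boot, "replicates (",
      x$n_failed, "failed ),", x$uncertainty, "uncertainty\n")
  invisible(x)
}

# MLE only (no profile intervals), for bootstrap replicates
fit_incarceration_rates <- function(cnt, eps = 1e-6) {
  obj <- function(p) loglik_counts(cnt$career_years, cnt$n_ever, cnt$n_never, p)
  p <- rep(0.1, 3)
  ll <- obj(p)
  for (cycle in 1:100) {
    for (k in 1:3) {
      o <- optimize(function(v) { p2 <- p; p2[k] <- v; obj(p2) },
                    interval = c(eps, 1 - eps), maximum = TRUE, tol = 1e-7)
      p[k] <- o$maximum
    }
    ll_new <- obj(p)
    if (ll_new - ll < 1e-9) break
    ll <- ll_new
  }
  setNames(p, c("p1", "p2", "p3"))
}
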