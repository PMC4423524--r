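#' Run the full initiation-and-replacement analysis pipeline
#'
#' Executes the analysis stages in order on a cohort (read from `input` or
#' generated from `config`): subgroup EFR estimation with bootstrap intervals,
#' the precision-weighted log-rate regression over the 12 non-regional
#' subgroups, piecewise incarceration fits (female, male, pooled), the
#' replacement rate per cessation scenario, and the unit-replacement quit
#' rates. Each stage's report is written as a plain comma-separated table to
#' `output_dir`, together with a machine-readable JSON run log recording the
#' seed, bootstrap settings, exclusion counts, a configuration hash and the
#' package version. Identical inputs produce byte-identical bundles; any
#' stage failure aborts with the stage name and removes partial outputs.
#'
#' @param input Path to a respondent table readable by [read_cohort()]
#'   (mutually exclusive with `config`).
#' @param config A [cohort_config()] to generate a synthetic cohort.
#' @param output_dir Directory for the report bundle (created if needed).
#' @param scenarios Tibble of cessation scenarios with columns `cessation`
#'   and optionally `quit` (`NA` or absent means `quit = cessation`).
#' @param n_boot Bootstrap resamples per subgroup.
#' @param level Confidence level throughout.
#' @param seed Integer seed for all resampling.
#' @param exclude_non_past_year Restrict EFR estimation to past-year
#'   injectors (sensitivity analysis; treats non-injectors' responsibility as
#'   zero by excluding them)?
#' @param replacement_ci_boot If > 0, also bootstrap a confidence interval
#'   for R per scenario with this many joint replicates (slower).
#' @return Invisibly, a list of class `efr_pipeline` with the report tibbles
#'   (`efr`, `regression`, `incarceration`, `incarceration_curve`,
#'   `replacement`, `quit_rates`) and the `log`.
#' @examples
#' \donttest{
#' out <- run_pipeline(config = cohort_config(n_respondents = 400, seed = 1),
#'                     output_dir = tempfile(), n_boot = 100, seed = 1)
#' out$replacement
#' }
#' @export
run_pipeline <- function(input = NULL, config = NULL, output_dir,
                         scenarios = tibble(cessation = c(0.05, 0.10, 0.15)),
                         n_boot = 1000, level = 0.95, seed,
                         exclude_non_past_year = FALSE,
                         replacement_ci_boot = 0) {
  if (missing(seed)) abort("`seed` must be given explicitly.")
  if (is.null(input) == is.null(config)) {
    abort("Give exactly one of `input` (a cohort file) or `config` (a cohort_config).")
  }
  if (!"cessation" %in% names(scenarios) || nrow(scenarios) == 0) {
    abort("`scenarios` must be a non-empty tibble with a `cessation` column.")
  }
  if (!"quit" %in% names(scenarios)) scenarios$quit <- NA_real_
  scenarios <- mutate(scenarios,
                      quit = ifelse(is.na(.data$quit), .data$cessation, .data$quit))

  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stage <- "setup"
  fail <- function(e) {
    unlink(written) # no partial bundles
    abort(paste0("Pipeline stage `", stage, "` failed: ", conditionMessage(e)),
          class = "efr_pipeline_error")
  }
  emit <- function(df, name) {
    path <- file.path(output_dir, name)
    readr::write_csv(df, path, na = "")
    written <<- base::c(written, path)
    df
  }

  result <- tryCatch({
    stage <- "cohort"
    records <- if (!is.null(input)) read_cohort(input) else generate_cohort(config)$records

    stage <- "efr"
    efr <- efr_table(records, keys = "report",
                     past_year_only = exclude_non_past_year,
                     n_boot = n_boot, level = level, seed = seed)
    emit(efr, "table1_efr.csv")
    efr12 <- efr_table(records, keys = "regression",
                       past_year_only = exclude_non_past_year,
                       n_boot = n_boot, level = level, seed = seed + 1000L)

    stage <- "regression"
    reg <- tidy(efr_regression(efr12), conf.level = level)
    emit(reg, "table2_regression.csv")

    stage <- "incarceration"
    fits <- list(F = fit_incarceration(records, sex = "F", level = level),
                 M = fit_incarceration(records, sex = "M", level = level),
                 overall = fit_incarceration(records, level = level))
    inc <- bind_rows(lapply(names(fits), function(s) {
      mutate(tidy(fits[[s]]), sex = s, .before = 1)
    }))
    emit(inc, "table3_incarceration.csv")
    curve <- bind_rows(lapply(names(fits), function(s) {
      mutate(incarceration_curve(fits[[s]]), sex = s, .before = 1)
    }))
    emit(curve, "figure2_curve.csv")

    stage <- "replacement"
    cells <- efr_table(records, keys = tidyr::crossing(
                         sex = NA_character_, region = NA_character_,
                         career_bin = CAREER_BINS, prison = c("never", "ever")),
                       past_year_only = exclude_non_past_year,
                       n_boot = n_boot, level = level, seed = seed + 2000L)
    lookup <- efr_lookup_from_estimates(cells)
    repl <- purrr::pmap(list(scenarios$cessation, scenarios$quit),
                        function(cs, qu) {
      r <- replacement_rate(lookup, fits$overall$rates, cessation = cs, quit = qu)
      row <- tibble(cessation = cs, quit = qu, R = r$R, f_value = r$f_value)
      if (replacement_ci_boot > 0) {
        ci <- replacement_ci(records, cessation = cs, quit = qu,
                             n_boot = replacement_ci_boot, level = level,
                             seed = seed + 3000L)
        row$R_low <- ci$ci["low"]; row$R_high <- ci$ci["high"]
      }
      row
    }) %>% bind_rows()
    emit(repl, "table4_replacement.csv")

    stage <- "quit_rates"
    quits <- purrr::map2(repl$cessation, repl$R, function(cs, R) {
      q <- quit_rate_for_unit_replacement(R, cs)
      tibble(cessation = cs, R = R, q_prime = q$q_prime,
             q_prime_nonneg = pmax(q$q_prime, 0),
             below_replacement = q$below_replacement)
    }) %>% bind_rows()
    emit(quits, "table5_quit.csv")

    stage <- "log"
    log <- list(
      seed = seed,
      n_boot = n_boot,
      level = level,
      n_respondents = nrow(records),
      n_initiators = sum(records$n_initiations_py > 0),
      n_dropped_missing_others = sum(records$n_initiations_py > 0 &
                                       is.na(records$n_others_recent)),
      exclude_non_past_year = exclude_non_past_year,
      scenarios = scenarios,
      config_hash = rlang::hash(list(if (is.null(input)) config else "file-input",
                                     scenarios, n_boot, level, seed,
                                     exclude_non_past_year)),
      package_version = as.character(utils::packageVersion("efrinit"))
    )
    log_path <- file.path(output_dir, "run_log.json")
    jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- base::c(written, log_path)

    structure(
      list(efr = efr, regression = reg, incarceration = inc,
           incarceration_curve = curve, replacement = repl,
           quit_rates = quits, log = log, output_dir = output_dir),
      class = "efr_pipeline"
    )
  }, error = fail)
  invisible(result)
}

#' @export
print.efr_pipeline <- function(x, ...) {
  cat("<efr_pipeline> reports in", x$output_dir, "\n")
  cat("  respondents:", x$log$n_respondents,
      " initiators:", x$log$n_initiators, "\n")
  cat("  replacement rates:\n")
  print(as.data.frame(x$replacement), digits = 3, row.names = FALSE)
  invisible(x)
}
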