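#' Configuration for the synthetic survey cohort generator
#'
#' Builds and validates the full parameter set that [generate_cohort()] needs
#' to emulate a NESI-like cross-sectional injector survey. Defaults are
#' calibrated once to the published survey summaries (see
#' [nesi_initiation_cells()] and [nesi_incarceration_rates()]): initiator
#' probability and mean initiation count per career-bin x prison cell come from
#' the published cell counts (replicated across sex, as the full 12-way table
#' is not published), incarceration rates by sex from the published
#' maximum-likelihood estimates, and the demographic mix from the survey's
#' marginal composition.
#'
#' @param n_respondents Number of survey records to generate.
#' @param prop_female Probability a respondent is female.
#' @param prop_region_ggc Probability a respondent is from Greater Glasgow and
#'   Clyde (vs elsewhere in Scotland).
#' @param prop_age_under35 Probability a respondent is aged under 35.
#' @param career_cessation_gen Per-annum geometric parameter controlling the
#'   career-length mix of the cross-sectional sample. This is a sampling knob,
#'   not an estimate: the career-length distribution of the surveyed population
#'   is not reliably inferable from the survey design.
#' @param career_cap_years Career lengths are capped at this many whole years.
#'   Must be at least 11 so all three incarceration-rate pieces are exercised.
#' @param incarceration_rates_by_sex Named list with elements `F` and `M`, each
#'   a numeric triple `(p1, p2, p3)` of per-annum first-incarceration
#'   probabilities for career years 1-5, 6-10 and 11+.
#' @param initiator_prob Tibble with columns `sex`, `career_bin`, `prison`,
#'   `prob`: probability of being present at >= 1 initiation in the past year,
#'   for each of the 12 sex x career-bin x prison cells.
#' @param initiation_count_mean Tibble with columns `sex`, `career_bin`,
#'   `prison`, `mean_count`: mean number of past-year initiations among
#'   initiators (must be >= 1; counts are 1 + geometric).
#' @param others_present_mean Poisson mean of the number of *other* injectors
#'   present at the most recent initiation (respondent and novice excluded).
#' @param prop_injected_past_year Probability a respondent injected in the past
#'   year.
#' @param missing_others_rate Probability an initiator's others-present answer
#'   is missing (missing completely at random).
#' @param missing_covariate_rate Probability a record has one of its
#'   demographic classifiers (sex, region, age group) blanked at random.
#' @param seed Integer seed; every generated cohort is fully reproducible from
#'   its config.
#'
#' @return A validated list of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_respondents = 500, seed = 1)
#' cfg$initiator_prob
#' @export
cohort_config <- function(n_respondents = 2500,
                          prop_female = 0.28,
                          prop_region_ggc = 0.37,
                          prop_age_under35 = 0.55,
                          career_cessation_gen = 0.0623,
                          career_cap_years = 40L,
                          incarceration_rates_by_sex = list(
                            F = nesi_incarceration_rates("female"),
                            M = nesi_incarceration_rates("male")
                          ),
                          initiator_prob = default_initiation_maps()$prob,
                          initiation_count_mean = default_initiation_maps()$mean,
                          others_present_mean = 2.5,
                          prop_injected_past_year = 0.85,
                          missing_others_rate = 0.016,
                          missing_covariate_rate = 0.01,
                          seed = 1L) {
  cfg <- list(
    n_respondents = n_respondents,
    prop_female = prop_female,
    prop_region_ggc = prop_region_ggc,
    prop_age_under35 = prop_age_under35,
    career_cessation_gen = career_cessation_gen,
    career_cap_years = as.integer(career_cap_years),
    incarceration_rates_by_sex = incarceration_rates_by_sex,
    initiator_prob = initiator_prob,
    initiation_count_mean = initiation_count_mean,
    others_present_mean = others_present_mean,
    prop_injected_past_year = prop_injected_past_year,
    missing_others_rate = missing_others_rate,
    missing_covariate_rate = missing_covariate_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

#' Default initiation-behaviour maps calibrated to published cell counts
#'
#' Initiator probability = initiators / respondents and mean past-year
#' initiation count among initiators = initiations / initiators, per
#' career-bin x prison cell of [nesi_initiation_cells()], replicated over sex.
#'
#' @return A list with tibbles `prob` and `mean`.
#' @export
default_initiation_maps <- function() {
  cells <- nesi_initiation_cells()
  base <- cells %>%
    mutate(
      prob = .data$n_initiators / .data$n_respondents,
      mean_count = .data$n_initiations / .data$n_initiators
    ) %>%
    select("career_bin", "prison", "prob", "mean_count")
  full <- tidyr::crossing(sex = c("F", "M"), base)
  list(
    prob = select(full, "sex", "career_bin", "prison", "prob"),
    mean = rename(select(full, "sex", "career_bin", "prison", "mean_count"),
                  mean_count = "mean_count")
  )
}

validate_cohort_config <- function(cfg) {
  if (!is.numeric(cfg$n_respondents) || length(cfg$n_respondents) != 1L ||
      is.na(cfg$n_respondents) || cfg$n_respondents < 1 ||
      cfg$n_respondents != floor(cfg$n_respondents)) {
    abort("`n_respondents` must be a positive integer.")
  }
  for (f in c("prop_female", "prop_region_ggc", "prop_age_under35",
              "career_cessation_gen", "prop_injected_past_year",
              "missing_others_rate", "missing_covariate_rate")) {
    check_prob(cfg[[f]], f)
  }
  if (cfg$career_cessation_gen <= 0) {
    abort("`career_cessation_gen` must be > 0 (else careers never end).")
  }
  if (is.na(cfg$career_cap_years) || cfg$career_cap_years < 11L) {
    abort("`career_cap_years` must be an integer >= 11 so that all three incarceration pieces are exercisable.")
  }
  rs <- cfg$incarceration_rates_by_sex
  if (!is.list(rs) || !all(c("F", "M") %in% names(rs))) {
    abort("`incarceration_rates_by_sex` must be a list with elements `F` and `M`.")
  }
  for (s in c("F", "M")) {
    p <- rs[[s]]
    if (!is.numeric(p) || length(p) != 3L || any(is.na(p)) || any(p < 0) || any(p > 1)) {
      abort("`incarceration_rates_by_sex` entries must be numeric triples of probabilities in [0, 1].")
    }
  }
  check_initiation_map(cfg$initiator_prob, "prob", "initiator_prob")
  check_initiation_map(cfg$initiation_count_mean, "mean_count", "initiation_count_mean")
  if (any(cfg$initiation_count_mean$mean_count < 1)) {
    abort("`initiation_count_mean` means must be >= 1 (counts are 1 + geometric).")
  }
  if (!is.numeric(cfg$others_present_mean) || cfg$others_present_mean < 0) {
    abort("`others_present_mean` must be a non-negative mean count.")
  }
  if (is.na(cfg$seed)) abort("`seed` must be an integer.")
  cfg
}

# every (sex, bin, prison) cell must be present exactly once with a valid value
check_initiation_map <- function(map, value_col, field) {
  needed <- c("sex", "career_bin", "prison", value_col)
  if (!is.data.frame(map) || !all(needed %in% names(map))) {
    abort(paste0("`", field, "` must be a data frame with columns ",
                 paste(needed, collapse = ", "), "."))
  }
  keys <- tidyr::crossing(sex = c("F", "M"), career_bin = CAREER_BINS,
                          prison = c("never", "ever"))
  found <- map %>%
    mutate(career_bin = as.character(.data$career_bin)) %>%
    distinct(.data$sex, .data$career_bin, .data$prison)
  if (nrow(found) != nrow(map) || nrow(dplyr::anti_join(keys, found,
      by = c("sex", "career_bin", "prison"))) > 0) {
    abort(paste0("`", field, "` must cover each (sex, career_bin, prison) cell exactly once."))
  }
  v <- map[[value_col]]
  if (!is.numeric(v) || any(is.na(v)) || any(v < 0)) {
    abort(paste0("`", field, "$", value_col, "` must be non-negative and non-missing."))
  }
  invisible(map)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  n_respondents:", x$n_respondents, " seed:", x$seed, "\n")
  cat("  prop_female:", x$prop_female, " prop_region_ggc:", x$prop_region_ggc, "\n")
  cat("  career knob:", x$career_cessation_gen, " cap:", x$career_cap_years, "years\n")
  cat("  incarceration p (F):", paste(x$incarceration_rates_by_sex$F, collapse = "/"),
      " (M):", paste(x$incarceration_rates_by_sex$M, collapse = "/"), "\n")
  cat("  others-present mean:", x$others_present_mean,
      " past-year injector:", x$prop_injected_past_year, "\n")
  invisible(x)
}
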