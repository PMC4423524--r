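#' Read and write respondent tables
#'
#' The on-disk interchange format is a plain comma-separated table with one
#' header row and columns `id, sex, region, age_group, career_years,
#' ever_incarcerated, injected_past_year, n_initiations_py, n_others_recent`.
#' Missing values are encoded as empty fields. `read_cohort(write_cohort(x))`
#' is an identity, including missingness markers, and writing the same records
#' twice produces byte-identical files.
#'
#' @param records A respondent tibble (or an `idu_cohort`, whose records are
#'   written).
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   a validated respondent tibble.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_respondents = 50, seed = 7))
#' f <- tempfile(fileext = ".csv")
#' write_cohort(cohort, f)
#' identical(read_cohort(f), cohort$records)
#' @export
write_cohort <- function(records, path) {
  if (inherits(records, "idu_cohort")) records <- records$records
  records <- validate_cohort_records(records)
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  spec <- readr::cols(
    id = readr::col_character(),
    sex = readr::col_character(),
    region = readr::col_character(),
    age_group = readr::col_character(),
    career_years = readr::col_integer(),
    ever_incarcerated = readr::col_logical(),
    injected_past_year = readr::col_logical(),
    n_initiations_py = readr::col_integer(),
    n_others_recent = readr::col_integer()
  )
  # parse problems surface through readr::problems() and the structural
  # validation below; readr's column-name warning would only duplicate them
  records <- suppressWarnings(
    readr::read_csv(path, col_types = spec, na = "", progress = FALSE)
  )
  missing_cols <- setdiff(names(spec$cols), names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("Malformed respondent table: missing columns ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  probs <- readr::problems(records)
  if (nrow(probs) > 0) {
    abort(paste0("Malformed respondent table: row ", probs$row[1], ", column `",
                 probs$col[1], "`: expected ", probs$expected[1], "."))
  }
  validate_cohort_records(records)
}

# structural validation shared by the reader and writer; errors name offending rows
validate_cohort_records <- function(records) {
  needed <- c("id", "sex", "region", "age_group", "career_years",
              "ever_incarcerated", "injected_past_year",
              "n_initiations_py", "n_others_recent")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("Respondent table is missing columns: ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  records <- as_tibble(records)[needed]

  bad_rows <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0) {
      abort(paste0("Invalid respondent table: ", what, " (rows ",
                   paste(utils::head(rows, 5), collapse = ", "),
                   if (length(rows) > 5) ", ..." else "", ")."))
    }
  }
  bad_rows(!is.na(records$sex) & !records$sex %in% c("F", "M"),
           "unknown sex code (expected F or M)")
  bad_rows(!is.na(records$region) & !records$region %in% c("GGC", "Else"),
           "unknown region code (expected GGC or Else)")
  bad_rows(!is.na(records$age_group) & !records$age_group %in% c("<35", ">=35"),
           "unknown age_group code (expected <35 or >=35)")
  bad_rows(is.na(records$career_years) | records$career_years < 0,
           "career_years must be a non-negative whole number of years")
  bad_rows(is.na(records$n_initiations_py) | records$n_initiations_py < 0,
           "n_initiations_py must be a non-negative count")
  bad_rows(!is.na(records$n_others_recent) & records$n_others_recent < 0,
           "n_others_recent must be a non-negative count or missing")
  bad_rows(records$n_initiations_py == 0 & !is.na(records$n_others_recent),
           "n_others_recent must be missing when n_initiations_py is 0 (question only asked of initiators)")
  records
}
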