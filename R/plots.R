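#' Plot subgroup EFR rates with bootstrap intervals
#'
#' Point estimates and percentile bootstrap intervals for each subgroup row
#' of an [efr_table()], on the per-annum EFR rate scale.
#'
#' @param object An `efr_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.efr_table <- function(object, ...) {
  lab <- apply(
    cbind(
      ifelse(is.na(object$sex), "", paste0(object$sex, " ")),
      ifelse(is.na(object$region), "", paste0(object$region, " ")),
      ifelse(is.na(object$career_bin), "", paste0(object$career_bin, "y ")),
      ifelse(is.na(object$prison), "all", object$prison)
    ),
    1, paste0, collapse = ""
  )
  df <- mutate(as_tibble(object), subgroup = factor(lab, levels = rev(unique(lab))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda_efr, y = .data$subgroup)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high)) +
    ggplot2::labs(
      x = expression(lambda[EFR] ~ "(initiations per annum)"),
      y = NULL,
      title = "Subgroup EFR initiation rates"
    ) +
    ggplot2::theme_minimal()
}
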