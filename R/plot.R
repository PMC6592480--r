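#' Diagnostic plot of the per-subject activity line
#'
#' Scatter of the selected (smoothed) minutes — activity energy expenditure
#' against heart rate — with the fitted regression line, a vertical line at
#' the age-predicted maximal heart rate, and the aEEmax intersection point.
#'
#' @param trace A `vo2_trace` tibble.
#' @param profile One cohort row with `subject_id`, `age`, `sex`.
#' @param config A [vo2_config()] list.
#' @return A ggplot object.
#' @export
plot_activity_fit <- function(trace, profile, config = vo2_config()) {
  config <- as_vo2_config(config)
  sel <- select_active_minutes(trace, config)
  feats <- extract_features(trace, profile, config)
  ggplot2::ggplot(sel, ggplot2::aes(x = .data$hr_smooth, y = .data$aee_smooth)) +
    ggplot2::geom_point(alpha = 0.4, colour = "grey30") +
    ggplot2::geom_abline(slope = feats$slope, intercept = feats$intercept,
                         colour = "steelblue", linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = feats$hrmax, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::annotate("point", x = feats$hrmax, y = feats$aeemax,
                      colour = "firebrick", size = 3) +
    ggplot2::labs(
      title = sprintf("Subject %s: aEEmax %.1f kcal/kg/h, slope %.3f",
                      feats$subject_id, feats$aeemax, feats$slope),
      x = "Smoothed heart rate (beats/min)",
      y = "Smoothed activity energy expenditure (kcal/kg/h)"
    ) +
    ggplot2::theme_minimal()
}

#' Measured vs estimated VO2max
#'
#' Scatter of measured against model-estimated VO2max with the identity
#' line, for a fitted model (uses its training data) or any model plus new
#' data.
#'
#' @param object A `vo2max_model`.
#' @param data Optional tibble with measured `vo2max` and the covariates;
#'   defaults to the model's training data.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vo2max_model <- function(object, data = NULL, ...) {
  data <- data %||% object$data
  if (is.null(data)) {
    abort("No data to plot: supply `data` for a published/loaded model.",
          class = "vo2_data_error")
  }
  est <- predict(object, data)
  df <- tibble::tibble(measured = as.numeric(data$vo2max), estimated = est)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$measured, y = .data$estimated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "firebrick") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Measured VO2max (mL/kg/min)",
                  y = "Estimated VO2max (mL/kg/min)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
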