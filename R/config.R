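#' Pipeline configuration
#'
#' Collects the tunable parameters of the trace-processing and modelling
#' pipeline in one list. Every parameter has a documented default; the
#' defaults reproduce the published processing chain.
#'
#' @param smooth_window_min Centred moving-average window for heart rate and
#'   activity energy expenditure, in minutes. Must be odd and positive.
#' @param hr_gate_bpm Heart-rate gate in beats/min: only minutes with smoothed
#'   heart rate strictly greater than this enter the per-subject regression.
#'   The published chain uses 120 beats/min, below which the heart-rate to
#'   activity relationship is nonlinear.
#' @param min_wear_minutes Minimum total wear time (minutes with both heart
#'   rate and activity present) required to attempt feature extraction.
#'   Default 900 minutes (15 hours).
#' @param min_days Expected trace span in calendar days; a shorter span
#'   produces a warning, not a failure.
#' @param min_points Minimum number of selected minutes required for the
#'   per-subject heart-rate/activity regression.
#' @param hrmax_female,hrmax_male Coefficients `c(intercept, per_year)` of the
#'   sex-specific age-predicted maximal heart rate, HRmax = intercept −
#'   per_year × age. Defaults: 200 − 0.67·age (female), 216 − 0.93·age (male).
#' @param see_p_denom Denominator for the cross-validated standard error of
#'   estimate: `"n"` for sqrt(PRESS/n) (default) or `"df"` for
#'   sqrt(PRESS/(n − p)).
#'
#' @return A named list of class `vo2_config`.
#' @examples
#' cfg <- vo2_config(smooth_window_min = 3)
#' cfg$hr_gate_bpm
#' @export
vo2_config <- function(smooth_window_min = 5L,
                       hr_gate_bpm = 120,
                       min_wear_minutes = 900L,
                       min_days = 3L,
                       min_points = 30L,
                       hrmax_female = c(intercept = 200, per_year = 0.67),
                       hrmax_male = c(intercept = 216, per_year = 0.93),
                       see_p_denom = c("n", "df")) {
  see_p_denom <- match.arg(see_p_denom)
  if (length(smooth_window_min) != 1L || is.na(smooth_window_min) ||
      smooth_window_min < 1 || smooth_window_min %% 2 == 0) {
    abort("`smooth_window_min` must be a positive odd integer.",
          class = "vo2_parameter_error")
  }
  if (hr_gate_bpm < 0) {
    abort("`hr_gate_bpm` must be nonnegative.", class = "vo2_parameter_error")
  }
  if (min_wear_minutes < 0) {
    abort("`min_wear_minutes` must be nonnegative.",
          class = "vo2_parameter_error")
  }
  structure(
    list(
      smooth_window_min = as.integer(smooth_window_min),
      hr_gate_bpm = as.numeric(hr_gate_bpm),
      min_wear_minutes = as.integer(min_wear_minutes),
      min_days = as.integer(min_days),
      min_points = as.integer(min_points),
      hrmax_female = as.numeric(hrmax_female),
      hrmax_male = as.numeric(hrmax_male),
      see_p_denom = see_p_denom
    ),
    class = "vo2_config"
  )
}

# internal: accept either a vo2_config or a plain list of overrides
as_vo2_config <- function(config) {
  if (inherits(config, "vo2_config")) return(config)
  if (is.null(config)) return(vo2_config())
  if (is.list(config)) return(do.call(vo2_config, config))
  abort("`config` must be a `vo2_config()` list.", class = "vo2_parameter_error")
}
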