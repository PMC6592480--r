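#' Age-predicted maximal heart rate
#'
#' Sex-specific population formulas: 200 − 0.67·age for women and
#' 216 − 0.93·age for men. No rounding is applied.
#'
#' @param age Age in years (> 0); vectorized.
#' @param sex "female" or "male" (recycled against `age`).
#' @param config Optional [vo2_config()] overriding the four formula
#'   constants via `hrmax_female` / `hrmax_male`.
#' @return Predicted maximal heart rate in beats/min.
#' @examples
#' predicted_hrmax(30, "female")  # 179.9
#' predicted_hrmax(50, "male")    # 169.5
#' @export
predicted_hrmax <- function(age, sex, config = vo2_config()) {
  config <- as_vo2_config(config)
  if (any(is.na(age)) || any(age <= 0)) {
    abort("`age` must be positive.", class = "vo2_parameter_error")
  }
  sex <- parse_sex(sex)
  n <- max(length(age), length(sex))
  age <- rep_len(as.numeric(age), n)
  sex <- rep_len(sex, n)
  f <- config$hrmax_female
  m <- config$hrmax_male
  ifelse(sex == "female", f[[1]] - f[[2]] * age, m[[1]] - m[[2]] * age)
}

#' Per-subject heart-rate/activity regression
#'
#' Ordinary least squares of activity energy expenditure on heart rate over
#' the selected minutes: `aee = slope × hr + intercept`. The slope (in
#' kcal/kg/h per beat/min) is itself one of the two trace-derived fitness
#' features.
#'
#' @param hr Selected (smoothed) heart-rate values, beats/min.
#' @param aee Selected (smoothed) activity values, kcal/kg/h.
#' @param min_points Minimum number of points required.
#' @return List with `slope`, `intercept`, `pearson_r_fit` (correlation of
#'   the per-subject fit) and `n_points`.
#' @export
fit_activity_line <- function(hr, aee, min_points = 30) {
  if (length(hr) != length(aee)) {
    abort("`hr` and `aee` must have the same length.", class = "vo2_data_error")
  }
  ok <- !is.na(hr) & !is.na(aee)
  hr <- hr[ok]
  aee <- aee[ok]
  n <- length(hr)
  if (n < min_points) {
    abort(sprintf("Too few regression points: %d available, %d required.",
                  n, as.integer(min_points)),
          class = "vo2_insufficiency_error", n_points = n)
  }
  sxx <- sum((hr - mean(hr))^2)
  if (sxx <= 0) {
    abort("Heart-rate values are all identical; the activity line is undefined.",
          class = "vo2_degenerate_error")
  }
  slope <- sum((hr - mean(hr)) * (aee - mean(aee))) / sxx
  intercept <- mean(aee) - slope * mean(hr)
  r <- if (sd(aee) > 0) cor(hr, aee) else NA_real_
  list(slope = slope, intercept = intercept, pearson_r_fit = r,
       n_points = as.integer(n))
}

#' Maximal activity energy expenditure from the fitted line
#'
#' aEEmax is the activity value at the intersection of the per-subject
#' regression line with the (age-predicted) maximal heart rate:
#' `slope × hrmax + intercept`. Negative or sub-resting values are returned
#' unchanged — flagging is the caller's job ([extract_features()] flags
#' values below 1 kcal/kg/h).
#'
#' @param slope Regression slope, kcal/kg/h per beat/min.
#' @param intercept Regression intercept, kcal/kg/h.
#' @param hrmax Maximal heart rate, beats/min.
#' @return aEEmax in kcal/kg/h.
#' @examples
#' aeemax_from_line(1.2, -80, 185)  # 142
#' @export
aeemax_from_line <- function(slope, intercept, hrmax) {
  if (any(!is.finite(slope)) || any(!is.finite(intercept)) ||
      any(!is.finite(hrmax))) {
    abort("`slope`, `intercept` and `hrmax` must be finite.",
          class = "vo2_parameter_error")
  }
  slope * hrmax + intercept
}

#' Extract the trace-derived fitness features for one subject
#'
#' Runs the full chain — sufficiency check, smoothing, co-increase selection,
#' heart-rate gate, per-subject regression, age-predicted HRmax — and returns
#' the two features (slope, aEEmax) plus diagnostics.
#'
#' @param trace A `vo2_trace` tibble for the subject.
#' @param profile One cohort row (tibble or list) with at least `subject_id`,
#'   `age` and `sex`.
#' @param config A [vo2_config()] list.
#' @return One-row tibble: `subject_id`, `hrmax`, `slope`, `intercept`,
#'   `aeemax`, `n_points`, `pearson_r_fit`, `n_wear_minutes`,
#'   `low_aeemax_flag` (aEEmax below the 1 kcal/kg/h resting level).
#' @export
extract_features <- function(trace, profile, config = vo2_config()) {
  config <- as_vo2_config(config)
  sid <- as.character(profile$subject_id %||% trace$subject_id[[1]])
  suff <- check_sufficiency(trace, config$min_wear_minutes, config$min_days)
  if (!suff$pass) {
    abort(sprintf("Subject %s: insufficient wear time (%d min < %d min).",
                  sid, suff$n_wear_minutes, config$min_wear_minutes),
          class = "vo2_insufficiency_error", subject_id = sid)
  }
  sel <- select_active_minutes(trace, config)
  line <- tryCatch(
    fit_activity_line(sel$hr_smooth, sel$aee_smooth, config$min_points),
    vo2_insufficiency_error = function(e) {
      abort(sprintf("Subject %s: only %d selected minutes (%d required).",
                    sid, nrow(sel), config$min_points),
            class = "vo2_insufficiency_error", subject_id = sid, parent = e)
    },
    vo2_degenerate_error = function(e) {
      abort(sprintf("Subject %s: degenerate activity-line fit.", sid),
            class = "vo2_degenerate_error", subject_id = sid, parent = e)
    }
  )
  hrmax <- predicted_hrmax(profile$age, profile$sex, config)
  aeemax <- aeemax_from_line(line$slope, line$intercept, hrmax)
  tibble::tibble(
    subject_id = sid,
    hrmax = hrmax,
    slope = line$slope,
    intercept = line$intercept,
    aeemax = aeemax,
    n_points = line$n_points,
    pearson_r_fit = line$pearson_r_fit,
    n_wear_minutes = suff$n_wear_minutes,
    low_aeemax_flag = aeemax < 1
  )
}

#' Extract features for a whole cohort
#'
#' Batch wrapper around [extract_features()]. Per-subject failures
#' (insufficient wear time, too few selected minutes, degenerate fits) never
#' abort the batch: failing subjects are collected in an exclusions table,
#' mirroring how cohort studies report excluded participants.
#'
#' @param traces Named list of `vo2_trace` tibbles (names = subject ids), or
#'   a character vector of trace CSV paths.
#' @param cohort A `vo2_cohort` tibble.
#' @param config A [vo2_config()] list.
#' @return List with `features` (tibble, one row per successful subject) and
#'   `exclusions` (tibble `subject_id`, `reason`).
#' @export
extract_features_batch <- function(traces, cohort, config = vo2_config()) {
  config <- as_vo2_config(config)
  if (is.character(traces)) {
    paths <- traces
    traces <- lapply(paths, read_trace)
    names(traces) <- purrr::map_chr(traces, ~ .x$subject_id[[1]])
  }
  if (is.null(names(traces)) || any(names(traces) == "")) {
    names(traces) <- purrr::map_chr(traces, ~ .x$subject_id[[1]])
  }
  rows <- list()
  excl <- list()
  for (i in seq_len(nrow(cohort))) {
    profile <- cohort[i, ]
    sid <- profile$subject_id
    tr <- traces[[sid]]
    if (is.null(tr)) {
      excl[[length(excl) + 1L]] <- tibble::tibble(
        subject_id = sid, reason = "no trace available")
      next
    }
    res <- tryCatch(
      extract_features(tr, profile, config),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      excl[[length(excl) + 1L]] <- tibble::tibble(subject_id = sid, reason = res)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  list(
    features = if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
      subject_id = character(), hrmax = double(), slope = double(),
      intercept = double(), aeemax = double(), n_points = integer(),
      pearson_r_fit = double(), n_wear_minutes = integer(),
      low_aeemax_flag = logical()),
    exclusions = if (length(excl)) dplyr::bind_rows(excl) else
      tibble::tibble(subject_id = character(), reason = character())
  )
}
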