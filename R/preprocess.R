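#' Segment-aware centred moving average
#'
#' Smooths a per-minute series with a centred moving average of odd width.
#' Contiguous runs of observed values (wear segments) are smoothed
#' independently: the window never crosses a gap, shrinks symmetrically-
#' truncated at segment edges, and missing minutes stay missing.
#'
#' @param x Numeric vector, `NA` marking non-wear minutes.
#' @param window Odd positive window width in minutes.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' moving_average(c(1, 2, 3, 4, 5), 3)  # 1.5 2 3 4 4.5
#' @export
moving_average <- function(x, window) {
  if (length(window) != 1L || is.na(window) || window < 1 || window %% 2 == 0) {
    abort("`window` must be a positive odd integer.",
          class = "vo2_parameter_error")
  }
  window <- as.integer(window)
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n == 0) return(out)
  half <- (window - 1L) %/% 2L
  seg <- segment_ids(!is.na(x))
  for (s in setdiff(unique(seg), 0L)) {
    idx <- which(seg == s)
    xs <- x[idx]
    m <- length(xs)
    cs <- cumsum(c(0, xs))
    i <- seq_len(m)
    lo <- pmax(1L, i - half)
    hi <- pmin(m, i + half)
    out[idx] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

# internal: label contiguous TRUE runs 1,2,...; FALSE positions get 0
segment_ids <- function(mask) {
  mask[is.na(mask)] <- FALSE
  starts <- mask & !c(FALSE, mask[-length(mask)])
  ids <- cumsum(starts)
  ids[!mask] <- 0L
  as.integer(ids)
}

#' Select co-increase minutes
#'
#' Differencing step of the processing chain: returns the indices `t` at
#' which both the heart-rate and the activity series strictly increased over
#' the previous minute (`x[t] − x[t−1] > 0` for both). The selected minute is
#' the later endpoint of the increasing step. Differences are only taken
#' within a contiguous wear segment (both values present at `t` and `t−1`);
#' a step across a non-wear gap is never selected.
#'
#' @param hr Smoothed heart-rate series, `NA` marking non-wear.
#' @param aee Smoothed activity series, same length, `NA` marking non-wear.
#' @return Sorted integer vector of selected indices.
#' @examples
#' select_coincrease(c(100, 105, 103, 110), c(2, 3, 4, 3))  # 2
#' @export
select_coincrease <- function(hr, aee) {
  if (length(hr) != length(aee)) {
    abort("`hr` and `aee` must have the same length.", class = "vo2_data_error")
  }
  n <- length(hr)
  if (n < 2) return(integer(0))
  wear <- !is.na(hr) & !is.na(aee)
  t <- 2:n
  ok <- wear[t] & wear[t - 1] &
    (hr[t] - hr[t - 1] > 0) & (aee[t] - aee[t - 1] > 0)
  ok[is.na(ok)] <- FALSE
  t[ok]
}

#' Apply the heart-rate gate
#'
#' Keeps only the indices whose heart rate is strictly greater than the
#' threshold. The published chain uses 120 beats/min to exclude the region
#' where heart rate and activity are nonlinearly related.
#'
#' @param idx Integer candidate indices.
#' @param hr Heart-rate series the indices refer to.
#' @param threshold Gate in beats/min (strict inequality).
#' @return The surviving subset of `idx`.
#' @export
apply_hr_gate <- function(idx, hr, threshold = 120) {
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0) {
    abort("`threshold` must be a nonnegative number.",
          class = "vo2_parameter_error")
  }
  if (length(idx) == 0) return(integer(0))
  keep <- !is.na(hr[idx]) & hr[idx] > threshold
  idx[keep]
}

#' Check data sufficiency of a trace
#'
#' A trace qualifies for feature extraction when it carries at least
#' `min_minutes` wear minutes (default 900 minutes = 15 hours). A span
#' shorter than `min_days` calendar days additionally produces a warning
#' in the diagnostics (and an R warning), but is not a failure.
#'
#' @param trace A `vo2_trace` tibble.
#' @param min_minutes Required wear minutes (default 900).
#' @param min_days Expected span in calendar days (default 3).
#' @return A list with `pass`, `n_wear_minutes`, `span_days`,
#'   `short_span_warning`.
#' @export
check_sufficiency <- function(trace, min_minutes = 900, min_days = 3) {
  if (min_minutes < 0) {
    abort("`min_minutes` must be nonnegative.", class = "vo2_parameter_error")
  }
  n_wear <- sum(trace$wear)
  days <- unique(as.Date(trace$timestamp, tz = "UTC"))
  span_days <- length(days)
  short <- span_days < min_days
  if (short) {
    warn(sprintf("Trace for %s spans %d calendar day(s); %d expected.",
                 trace$subject_id[[1]] %||% "?", span_days, as.integer(min_days)),
         class = "vo2_short_span_warning")
  }
  list(
    pass = n_wear >= min_minutes,
    n_wear_minutes = as.integer(n_wear),
    span_days = as.integer(span_days),
    short_span_warning = short
  )
}

#' Run the minute-selection chain on a trace
#'
#' Applies the full signal-processing chain — centred moving average on both
#' series (within wear segments), co-increase selection, heart-rate gate —
#' and returns the minutes that enter the per-subject heart-rate/activity
#' regression, with their smoothed values.
#'
#' @param trace A `vo2_trace` tibble.
#' @param config A [vo2_config()] list (or a list of overrides).
#' @return A tibble with columns `timestamp`, `hr`, `aee`, `hr_smooth`,
#'   `aee_smooth` (one row per selected minute), carrying a `"selection"`
#'   attribute: list with `n_wear_minutes`, `n_coincrease`, `n_after_hr_gate`,
#'   `hr_threshold`, `selected_idx`.
#' @export
select_active_minutes <- function(trace, config = vo2_config()) {
  config <- as_vo2_config(config)
  hr_in <- ifelse(trace$wear, trace$hr, NA_real_)
  aee_in <- ifelse(trace$wear, trace$aee, NA_real_)
  hr_s <- moving_average(hr_in, config$smooth_window_min)
  aee_s <- moving_average(aee_in, config$smooth_window_min)
  idx_ci <- select_coincrease(hr_s, aee_s)
  idx <- apply_hr_gate(idx_ci, hr_s, config$hr_gate_bpm)
  out <- tibble::tibble(
    timestamp = trace$timestamp[idx],
    hr = trace$hr[idx],
    aee = trace$aee[idx],
    hr_smooth = hr_s[idx],
    aee_smooth = aee_s[idx]
  )
  attr(out, "selection") <- list(
    n_wear_minutes = as.integer(sum(trace$wear)),
    n_coincrease = length(idx_ci),
    n_after_hr_gate = length(idx),
    hr_threshold = config$hr_gate_bpm,
    selected_idx = idx
  )
  out
}
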