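#' Reference cohort group parameters
#'
#' Per-stratum (sex × age band) means and SDs of the anthropometric and
#' trace-derived variables used as simulator defaults: height (cm), weight
#' (kg), percent body fat, aEEmax (kcal/kg/h), slope (kcal/kg/h/bpm) and
#' measured VO2max (mL/kg/min), with the stratum sizes of the 191-subject
#' development cohort.
#'
#' @return Tibble with one row per stratum.
#' @export
cohort_group_params <- function() {
  tibble::tribble(
    ~sex,     ~age_min, ~age_max, ~n,
    ~height_mean, ~height_sd, ~weight_mean, ~weight_sd,
    ~fat_mean, ~fat_sd, ~aeemax_mean, ~aeemax_sd,
    ~slope_mean, ~slope_sd, ~vo2max_mean, ~vo2max_sd,
    "male",   20, 35, 34, 174.3, 5.6, 73.9, 8.0, 20.4, 5.2, 141.0, 14.6, 1.10, 0.14, 42.3, 3.6,
    "male",   36, 50, 26, 172.6, 6.1, 74.7, 9.7, 24.8, 4.9, 123.7, 15.1, 1.04, 0.13, 39.9, 3.5,
    "male",   51, 65, 30, 167.1, 4.9, 67.0, 6.1, 24.2, 5.1, 111.2, 11.0, 1.04, 0.12, 38.1, 4.6,
    "female", 20, 35, 36, 161.9, 5.4, 55.8, 7.3, 29.4, 6.7, 112.5, 15.8, 0.92, 0.17, 35.3, 3.5,
    "female", 36, 50, 35, 160.0, 5.2, 60.6, 6.1, 33.9, 4.9, 107.7, 12.1, 0.98, 0.14, 31.4, 4.1,
    "female", 51, 65, 30, 155.3, 4.8, 56.2, 6.1, 33.8, 5.4, 102.0, 10.3, 0.96, 0.13, 30.5, 3.9
  )
}

#' Simulator configuration
#'
#' All knobs of the synthetic cohort/trace generator, each with a documented
#' default. The seed is mandatory: identical config + seed produce
#' bit-identical output.
#'
#' @param seed Integer RNG seed (required; no implicit entropy).
#' @param group_params Per-stratum parameter tibble; defaults to
#'   [cohort_group_params()].
#' @param n_per_group Either `NULL` (use each stratum's reference `n`,
#'   total 191) or a single count applied to every stratum.
#' @param days Trace length in days (default 3).
#' @param wear_hours_per_day Wear window length, hours/day (default 14:
#'   the device is off during sleep and showering).
#' @param bout_rate Activity bouts per day (default 5).
#' @param ramp_bpm_per_min Heart-rate ramp rate during a bout, beats/min per
#'   minute (default 2; kept at or below 5 so that a centred 5-minute
#'   smoothing window around any above-gate minute stays inside the linear
#'   heart-rate regime).
#' @param peak_fracs Bout peak heart rates as fractions of the above-gate
#'   reserve: peak = 120 + frac × (HRmax − 120); the fractions cycle over
#'   the day's bouts (default 0.35, 0.55, 0.75, 0.90, 0.99, so bouts reach
#'   high fractions of the subject's aEEmax).
#' @param hr_rest_bpm Resting heart rate (default 70).
#' @param aee_rest Resting activity energy expenditure, kcal/kg/h (default
#'   1.0, one MET).
#' @param linear_break_bpm Heart rate above which the activity response is
#'   exactly linear (default 110); below it the response is a deliberately
#'   nonlinear (quadratic, flattened-at-rest) curve, reproducing the
#'   low-heart-rate nonlinearity that motivates the 120 beats/min gate.
#' @param hr_noise_sd,aee_noise_sd Per-minute Gaussian noise SDs on heart
#'   rate (beats/min, default 2) and activity (kcal/kg/h, default 2) —
#'   minute-level tracker output is already internally averaged, so the
#'   residual jitter is small.
#' @param vo2max_noise_sd SD of the measured-VO2max noise around the
#'   generative linear model, mL/kg/min (default 3.5).
#' @param coefficients Generative VO2max coefficients, named like the model
#'   terms; default: the published coefficient vector.
#' @param trunc_sd Covariate draws are truncated at ± this many SDs
#'   (default 3), avoiding physiologically absurd subjects.
#' @return Named list of class `vo2_sim_config`.
#' @export
sim_config <- function(seed,
                       group_params = cohort_group_params(),
                       n_per_group = NULL,
                       days = 3,
                       wear_hours_per_day = 14,
                       bout_rate = 5,
                       ramp_bpm_per_min = 2,
                       peak_fracs = c(0.35, 0.55, 0.75, 0.90, 0.99),
                       hr_rest_bpm = 70,
                       aee_rest = 1.0,
                       linear_break_bpm = 110,
                       hr_noise_sd = 2,
                       aee_noise_sd = 2,
                       vo2max_noise_sd = 3.5,
                       coefficients = coef(published_model()),
                       trunc_sd = 3) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    abort("`seed` is required and must be an integer.",
          class = "vo2_parameter_error")
  }
  sds <- c(hr_noise_sd, aee_noise_sd, vo2max_noise_sd,
           unlist(group_params[grep("_sd$", names(group_params))]))
  if (any(sds < 0)) {
    abort("All noise/spread SDs must be nonnegative.",
          class = "vo2_parameter_error")
  }
  if (!is.null(n_per_group) && any(n_per_group < 1)) {
    abort("`n_per_group` must be at least 1.", class = "vo2_parameter_error")
  }
  if (linear_break_bpm <= hr_rest_bpm) {
    abort("`linear_break_bpm` must exceed the resting heart rate.",
          class = "vo2_parameter_error")
  }
  structure(
    list(seed = as.integer(seed), group_params = group_params,
         n_per_group = n_per_group, days = as.integer(days),
         wear_hours_per_day = wear_hours_per_day, bout_rate = as.integer(bout_rate),
         ramp_bpm_per_min = ramp_bpm_per_min, peak_fracs = peak_fracs,
         hr_rest_bpm = hr_rest_bpm, aee_rest = aee_rest,
         linear_break_bpm = linear_break_bpm,
         hr_noise_sd = hr_noise_sd, aee_noise_sd = aee_noise_sd,
         vo2max_noise_sd = vo2max_noise_sd,
         coefficients = coefficients, trunc_sd = trunc_sd),
    class = "vo2_sim_config"
  )
}

# internal: normal draw truncated at mean ± k*sd (rejection sampling;
# sd = 0 degenerates to the mean)
rnorm_trunc <- function(n, mean, sd, k) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  for (iter in 1:100) {
    bad <- abs(x - mean) > k * sd
    if (!any(bad)) break
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x
}

#' Simulate a cohort with known ground truth
#'
#' Draws subject covariates per stratum from truncated normal distributions
#' around the configured group means, assigns each subject a true activity
#' slope, aEEmax, age-predicted HRmax and the implied line intercept
#' (intercept = aEEmax − slope × HRmax), and sets measured VO2max to the
#' generative linear combination of covariates plus Gaussian noise.
#'
#' @param config A [sim_config()].
#' @return List with `profiles` (a `vo2_cohort` tibble including measured
#'   `vo2max`) and `truth` (per-subject `true_slope`, `true_intercept`,
#'   `true_aeemax`, `true_hrmax`, `true_vo2max` — the noiseless linear
#'   predictor — and a derived `trace_seed`), with the generative
#'   coefficients attached as attribute `"coefficients"`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "vo2_sim_config"))
  set.seed(config$seed)
  gp <- config$group_params
  k <- config$trunc_sd
  rows <- purrr::pmap(gp, function(sex, age_min, age_max, n, height_mean,
                                   height_sd, weight_mean, weight_sd, fat_mean,
                                   fat_sd, aeemax_mean, aeemax_sd, slope_mean,
                                   slope_sd, vo2max_mean, vo2max_sd) {
    m <- if (is.null(config$n_per_group)) n else config$n_per_group
    tibble::tibble(
      sex = sex,
      age = sample(seq(age_min, age_max), m, replace = TRUE),
      height = rnorm_trunc(m, height_mean, height_sd, k),
      weight = rnorm_trunc(m, weight_mean, weight_sd, k),
      percent_body_fat = rnorm_trunc(m, fat_mean, fat_sd, k),
      aeemax = rnorm_trunc(m, aeemax_mean, aeemax_sd, k),
      slope = rnorm_trunc(m, slope_mean, slope_sd, k)
    )
  })
  sub <- dplyr::bind_rows(rows)
  n_total <- nrow(sub)
  sub$subject_id <- sprintf("S%03d", seq_len(n_total))
  sub$hrmax <- predicted_hrmax(sub$age, sub$sex)
  co <- config$coefficients
  linpred <- co[["constant"]] + co[["aeemax"]] * sub$aeemax +
    co[["slope"]] * sub$slope + co[["percent_body_fat"]] * sub$percent_body_fat +
    co[["age"]] * sub$age + co[["sex"]] * (sub$sex == "male") +
    co[["height"]] * sub$height
  vo2max_measured <- linpred + rnorm(n_total, 0, config$vo2max_noise_sd)
  profiles <- tibble::tibble(
    subject_id = sub$subject_id, age = as.numeric(sub$age), sex = sub$sex,
    height = sub$height, weight = sub$weight,
    percent_body_fat = sub$percent_body_fat, vo2max = vo2max_measured
  )
  class(profiles) <- c("vo2_cohort", class(profiles))
  truth <- tibble::tibble(
    subject_id = sub$subject_id,
    true_slope = sub$slope,
    true_intercept = sub$aeemax - sub$slope * sub$hrmax,
    true_aeemax = sub$aeemax,
    true_hrmax = sub$hrmax,
    true_vo2max = linpred,
    trace_seed = sample.int(.Machine$integer.max - 1L, n_total)
  )
  attr(truth, "coefficients") <- co
  list(profiles = profiles, truth = truth)
}

# internal: clean (noiseless) activity response to heart rate.
# Exactly linear at/above the breakpoint; below it a quadratic curve from
# the resting level to the line, continuous at the breakpoint.
aee_response <- function(hr, slope, intercept, config) {
  brk <- config$linear_break_bpm
  rest_hr <- config$hr_rest_bpm
  rest_aee <- config$aee_rest
  l_brk <- slope * brk + intercept
  frac <- pmin(1, pmax(0, (hr - rest_hr) / (brk - rest_hr)))
  ifelse(hr >= brk,
         slope * hr + intercept,
         rest_aee + (l_brk - rest_aee) * frac^2)
}

# internal: clean heart-rate profile for one wear day (minutes within the
# wear window). Bouts ramp up at ramp_bpm_per_min to the cycled peak, hold
# 2 minutes, then descend at twice the ramp rate.
day_hr_profile <- function(wear_min, hrmax, config) {
  hr <- rep(config$hr_rest_bpm, wear_min)
  n_bouts <- config$bout_rate
  if (n_bouts < 1) return(hr)
  fracs <- rep_len(config$peak_fracs, n_bouts)
  gap <- wear_min / n_bouts
  up <- config$ramp_bpm_per_min
  down <- 2 * up
  for (b in seq_len(n_bouts)) {
    peak <- 120 + fracs[b] * (hrmax - 120)
    rise <- ceiling((peak - config$hr_rest_bpm) / up)
    hold <- 2L
    fall <- ceiling((peak - config$hr_rest_bpm) / down)
    start <- floor((b - 1) * gap) + 5L
    prof <- c(config$hr_rest_bpm + up * seq_len(rise - 1), peak,
              rep(peak, hold),
              pmax(config$hr_rest_bpm, peak - down * seq_len(fall)))
    stop_at <- min(wear_min, start + length(prof) - 1L)
    if (start <= stop_at) {
      hr[start:stop_at] <- pmin(prof[seq_len(stop_at - start + 1L)], hrmax)
    }
  }
  hr
}

#' Simulate a minute-level trace for one subject
#'
#' Generates `days` days of minute-indexed heart rate and activity energy
#' expenditure. Each day has a single wear window (default 14 h starting at
#' 08:00); minutes outside it are non-wear (both channels missing). Within
#' the window the subject rests at the resting heart rate / 1 kcal/kg/h,
#' interrupted by `bout_rate` ramped activity bouts. Wherever the clean
#' heart rate is at or above `linear_break_bpm`, the clean activity value is
#' exactly `true_slope × hr + true_intercept`; below it the response is
#' nonlinear, so the 120 beats/min gate genuinely matters. Independent
#' Gaussian noise is then added to both channels.
#'
#' @param truth One row of the `truth` tibble from [simulate_cohort()] (or
#'   any list with `subject_id`, `true_slope`, `true_intercept`,
#'   `true_hrmax`, `trace_seed`).
#' @param config A [sim_config()].
#' @return A `vo2_trace` tibble of `days × 1440` minutes.
#' @export
simulate_trace <- function(truth, config) {
  stopifnot(inherits(config, "vo2_sim_config"))
  if (truth$true_slope <= 0) {
    abort("`true_slope` must be positive.", class = "vo2_parameter_error")
  }
  set.seed(truth$trace_seed %||% config$seed)
  minutes_per_day <- 1440L
  wear_min <- as.integer(round(config$wear_hours_per_day * 60))
  wear_start <- 8L * 60L  # wear window opens at 08:00
  n <- config$days * minutes_per_day
  hr_clean <- rep(NA_real_, n)
  for (d in seq_len(config$days)) {
    off <- (d - 1L) * minutes_per_day + wear_start
    hr_clean[(off + 1L):(off + wear_min)] <-
      day_hr_profile(wear_min, truth$true_hrmax, config)
  }
  wear <- !is.na(hr_clean)
  aee_clean <- rep(NA_real_, n)
  aee_clean[wear] <- aee_response(hr_clean[wear], truth$true_slope,
                                  truth$true_intercept, config)
  hr <- hr_clean
  aee <- aee_clean
  if (config$hr_noise_sd > 0) {
    hr[wear] <- pmax(30, hr[wear] + rnorm(sum(wear), 0, config$hr_noise_sd))
  }
  if (config$aee_noise_sd > 0) {
    aee[wear] <- pmax(0, aee[wear] + rnorm(sum(wear), 0, config$aee_noise_sd))
  }
  t0 <- as.POSIXct("2023-01-09 00:00:00", tz = "UTC")
  new_trace(truth$subject_id, t0 + 60 * (seq_len(n) - 1L), hr, aee)
}

#' Simulate a full study: cohort plus traces
#'
#' Convenience wrapper: [simulate_cohort()] followed by [simulate_trace()]
#' for every subject.
#'
#' @param config A [sim_config()].
#' @return List with `profiles`, `truth` and `traces` (named list of
#'   `vo2_trace` tibbles).
#' @export
simulate_study <- function(config) {
  cohort <- simulate_cohort(config)
  traces <- purrr::map(seq_len(nrow(cohort$truth)), function(i) {
    simulate_trace(cohort$truth[i, ], config)
  })
  names(traces) <- cohort$truth$subject_id
  c(cohort, list(traces = traces))
}
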