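test_that("age-predicted maximal heart rate follows the sex-specific formulas", {
  expect_equal(predicted_hrmax(30, "female"), 179.9)
  expect_equal(predicted_hrmax(50, "male"), 169.5)
  expect_equal(predicted_hrmax(20, "female"), 186.6)
  expect_equal(predicted_hrmax(c(30, 50), c("female", "male")), c(179.9, 169.5))
  expect_error(predicted_hrmax(0, "male"), class = "vo2_parameter_error")

  # strictly decreasing in age for both sexes
  ages <- 20:65
  for (s in c("female", "male")) {
    hm <- predicted_hrmax(ages, s)
    expect_true(all(diff(hm) < 0))
  }
})

test_that("activity line fit matches a normal-equations oracle", {
  # noiseless line recovered exactly
  hr <- seq(125, 180, by = 1)
  fit <- fit_activity_line(hr, 1.2 * hr - 80, min_points = 30)
  expect_equal(fit$slope, 1.2, tolerance = 1e-12)
  expect_equal(fit$intercept, -80, tolerance = 1e-10)

  # insufficiency and degeneracy
  expect_error(fit_activity_line(c(130, 140), c(70, 80), min_points = 30),
               class = "vo2_insufficiency_error")
  expect_error(fit_activity_line(rep(130, 40), rnorm(40, 75), min_points = 30),
               class = "vo2_degenerate_error")

  # 50 noisy points against the closed-form least-squares solution
  set.seed(21)
  hr <- runif(50, 121, 185)
  aee <- 1.1 * hr - 70 + rnorm(50, 0, 4)
  fit <- fit_activity_line(hr, aee, min_points = 30)
  X <- cbind(1, hr)
  beta <- solve(t(X) %*% X, t(X) %*% aee)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  expect_equal(fit$pearson_r_fit, cor(hr, aee), tolerance = 1e-12)
})

test_that("aEEmax is the line evaluated at maximal heart rate", {
  expect_equal(aeemax_from_line(1.0, 0, 150), 150)
  expect_equal(aeemax_from_line(1.2, -80, 185), 142)
  expect_equal(aeemax_from_line(0, 3.3, 190), 3.3)  # flat-line edge
  expect_error(aeemax_from_line(Inf, 0, 150), class = "vo2_parameter_error")
  # strictly increasing in hrmax for positive slope
  expect_true(all(diff(aeemax_from_line(1.1, -70, seq(150, 200, 10))) > 0))
})

test_that("scaling activity by c > 0 scales slope, intercept and aEEmax by c", {
  cfg <- sim_config(seed = 22, hr_noise_sd = 0, aee_noise_sd = 0)
  ch <- simulate_cohort(cfg)
  tr <- simulate_trace(ch$truth[5, ], cfg)
  profile <- ch$profiles[5, ]
  f1 <- extract_features(tr, profile)
  tr_scaled <- tr
  tr_scaled$aee <- tr$aee * 2.5
  f2 <- extract_features(tr_scaled, profile)
  expect_equal(f2$slope, 2.5 * f1$slope, tolerance = 1e-10)
  expect_equal(f2$intercept, 2.5 * f1$intercept, tolerance = 1e-10)
  expect_equal(f2$aeemax, 2.5 * f1$aeemax, tolerance = 1e-10)
})

test_that("feature extraction satisfies its construction invariant and error contracts", {
  cfg <- sim_config(seed = 23)
  ch <- simulate_cohort(cfg)
  tr <- simulate_trace(ch$truth[3, ], cfg)
  f <- extract_features(tr, ch$profiles[3, ])
  expect_equal(f$aeemax, f$slope * f$hrmax + f$intercept, tolerance = 1e-12)
  expect_gte(f$n_points, 30)
  expect_gt(f$hrmax, 120)

  # a trace that never exceeds the gate has no regression points
  hr <- rep(c(80, 85, 90, 95, 100), 200)
  flat <- make_trace(hr, hr / 50, start = "2023-01-09 00:00:00")
  suppressWarnings(
    expect_error(extract_features(flat, list(subject_id = "F", age = 30,
                                             sex = "female")),
                 class = "vo2_insufficiency_error"))

  # too little wear time is rejected before any selection
  tiny <- make_trace(rep(130, 100), rep(60, 100))
  suppressWarnings(
    expect_error(extract_features(tiny, list(subject_id = "T", age = 30,
                                             sex = "male")),
                 class = "vo2_insufficiency_error"))
})

test_that("batch extraction reports exclusions without aborting", {
  cfg <- sim_config(seed = 24)
  ch <- simulate_cohort(sim_config(seed = 24, n_per_group = 1))
  traces <- purrr::map(seq_len(nrow(ch$truth)),
                       ~ simulate_trace(ch$truth[.x, ], cfg))
  names(traces) <- ch$truth$subject_id
  # cripple one subject's trace: wear below the 900-minute floor
  traces[[2]] <- traces[[2]][1:200, ]
  suppressWarnings(res <- extract_features_batch(traces, ch$profiles))
  expect_equal(nrow(res$features), 5)
  expect_equal(nrow(res$exclusions), 1)
  expect_equal(res$exclusions$subject_id, ch$profiles$subject_id[2])
  expect_match(res$exclusions$reason, "insufficient wear")
})
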