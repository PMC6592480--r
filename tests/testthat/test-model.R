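test_that("a noiseless linear response is identified exactly", {
  truth <- coef(published_model())
  tbl <- make_model_table(n = 60, seed = 41, noise_sd = 0, coefs = truth)
  m <- fit_vo2max_model(tbl)
  expect_equal(m$coefficients, truth, tolerance = 1e-8)
  expect_equal(m$metrics$see, 0, tolerance = 1e-8)
  expect_equal(m$metrics$r, 1, tolerance = 1e-10)
  expect_equal(m$metrics$r2, m$metrics$r^2, tolerance = 1e-12)
})

test_that("degenerate or incomplete designs raise classed errors", {
  tbl <- make_model_table(n = 40, seed = 42, noise_sd = 2)
  dup <- tbl
  dup$height <- dup$age  # duplicated covariate column
  expect_error(fit_vo2max_model(dup), class = "vo2_degenerate_error")

  incomplete <- tbl
  incomplete$aeemax[3] <- NA
  expect_error(fit_vo2max_model(incomplete), class = "vo2_data_error")
  expect_error(fit_vo2max_model(tbl["vo2max"]), class = "vo2_data_error")
})

test_that("the published model predicts the worked example and the exact sex offset", {
  m <- published_model()
  expect_equal(coef(m)[["constant"]], 63.262)
  expect_equal(coef(m)[["sex"]], 3.264)
  expect_equal(m$metrics$see, 3.518)
  expect_equal(m$metrics$r_p, 0.787)

  expect_equal(predict(m, worked_example_covariates("male")), 43.7056,
               tolerance = 1e-9)
  # intercept only: all covariates zero, female
  zero <- tibble::tibble(aeemax = 0, slope = 0, percent_body_fat = 0,
                         age = 1e-12, sex = "female", height = 0)
  expect_equal(predict(m, zero), 63.262, tolerance = 1e-9)
  # male vs female differ by exactly the sex coefficient
  expect_equal(predict(m, worked_example_covariates("male")) -
                 predict(m, worked_example_covariates("female")),
               3.264, tolerance = 1e-12)
})

test_that("predict is affine in every covariate", {
  m <- published_model()
  base <- worked_example_covariates()
  p0 <- predict(m, base)
  for (v in c("aeemax", "slope", "percent_body_fat", "age", "height")) {
    shifted <- base
    shifted[[v]] <- shifted[[v]] + 2.5
    expect_equal(predict(m, shifted) - p0, 2.5 * coef(m)[[v]],
                 tolerance = 1e-12, info = v)
  }
})

test_that("missing covariate values yield flagged NA predictions", {
  m <- published_model()
  nd <- worked_example_covariates()
  nd$percent_body_fat <- NA
  expect_warning(p <- predict(m, nd),
                 class = "vo2_missing_covariate_warning")
  expect_true(is.na(p))
  expect_error(predict(m, nd[, setdiff(names(nd), "height")]),
               class = "vo2_data_error")
})

test_that("closed-form PRESS equals brute-force leave-one-out refitting", {
  for (seed in 1:8) {
    prob <- random_design(n = 10 + 4 * seed, p = 6, seed = 300 + seed)
    cv <- press_cv(prob$X, prob$y)
    expect_equal(cv$press, press_brute_force(prob$X, prob$y),
                 tolerance = 1e-8)
  }
  # exact linear response: zero leave-one-out error
  prob <- random_design(n = 30, p = 6, seed = 99)
  y_exact <- as.numeric(cbind(1, prob$X) %*% rep(1, 7))
  cv <- press_cv(prob$X, y_exact)
  expect_equal(cv$press, 0, tolerance = 1e-16)
  expect_equal(cv$r_p, 1)
})

test_that("a case with leverage one is refused by name", {
  # an indicator covariate lighting up only case 1 pins its leverage at 1
  X <- cbind(flag = c(1, 0, 0, 0, 0), x = c(2, 4, 1, 5, 3))
  y <- c(10, 2, 4, 1, 3)
  err <- expect_error(press_cv(X, y), class = "vo2_degenerate_error")
  expect_match(conditionMessage(err), "case\\(s\\) 1")
})

test_that("cross-validated metrics never beat the in-sample metrics", {
  for (seed in c(7, 19, 55)) {
    tbl <- make_model_table(n = 50 + seed, seed = seed, noise_sd = 3.5)
    m <- fit_vo2max_model(tbl)
    expect_gte(m$metrics$see_p, m$metrics$see)
    expect_lte(m$metrics$r_p, m$metrics$r)
    expect_gte(m$metrics$press, sum(m$data$.resid^2))
  }
})

test_that("constant error vanishes overall and within included indicator levels", {
  tbl <- make_model_table(n = 80, seed = 56, noise_sd = 3.5)
  m <- fit_vo2max_model(tbl)
  rep <- subgroup_validation(m, tbl)
  overall <- rep[rep$split == "overall", ]
  expect_lt(abs(overall$ce), 1e-8)
  for (g in c("female", "male")) {
    expect_lt(abs(rep$ce[rep$split == "sex" & rep$group == g]), 1e-8)
  }
  # subgroup sizes within each split sum to the cohort size
  for (s in c("sex", "age", "vo2max")) {
    expect_equal(sum(rep$n[rep$split == s]), nrow(tbl))
  }
})

test_that("fitness splits show the regression-to-the-mean sign pattern", {
  tbl <- make_model_table(n = 120, seed = 57, noise_sd = 3.5)
  m <- fit_vo2max_model(tbl)
  rep <- subgroup_validation(m, tbl)
  expect_gt(rep$ce[rep$split == "vo2max" & rep$group == "high"], 0)
  expect_lt(rep$ce[rep$split == "vo2max" & rep$group == "low"], 0)
  # overridable fixed cuts are honoured
  rep40 <- subgroup_validation(m, tbl, age_cut = 40, vo2max_cut = 36)
  cuts <- attr(rep40, "cuts")
  expect_equal(cuts$age_cut, 40)
  expect_equal(cuts$vo2max_cut, 36)
  expect_equal(rep40$n[rep40$split == "age" & rep40$group == "old"],
               sum(tbl$age > 40))
})

test_that("correlation table matches the closed-form Pearson oracle", {
  tbl <- make_model_table(n = 5, seed = 58, noise_sd = 1)
  ct <- correlation_table(tbl)
  # direct covariance-formula oracle on one pair
  x <- tbl$vo2max; y <- tbl$aeemax
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- ct$r[ct$var1 == "vo2max" & ct$var2 == "aeemax"]
  expect_equal(got, r_oracle, tolerance = 1e-12)
  expect_equal(nrow(ct), choose(7, 2))

  # exactly anti-linear pair
  tbl2 <- make_model_table(n = 10, seed = 59, noise_sd = 1)
  tbl2$slope <- -2 * tbl2$aeemax + 5
  ct2 <- correlation_table(tbl2)
  expect_equal(ct2$r[ct2$var1 == "aeemax" & ct2$var2 == "slope"], -1,
               tolerance = 1e-12)

  # zero-variance column flagged as undefined
  tbl3 <- make_model_table(n = 10, seed = 60, noise_sd = 1)
  tbl3$height <- 170
  ws <- capture_warnings(ct3 <- correlation_table(tbl3))
  expect_true(all(grepl("Zero variance", ws)))
  expect_length(ws, 6)  # every pair involving the constant column
  expect_true(is.na(ct3$r[ct3$var1 == "height" & ct3$var2 == "aeemax"]))
})

test_that("tidy and glance expose the coefficient table and metric block", {
  tbl <- make_model_table(n = 40, seed = 61, noise_sd = 2)
  m <- fit_vo2max_model(tbl)
  td <- tidy(m)
  expect_equal(td$term, c("constant", "aeemax", "slope", "percent_body_fat",
                          "age", "sex", "height"))
  expect_equal(td$estimate, unname(coef(m)))
  gl <- glance(m)
  expect_equal(gl$n, 40L)
  expect_equal(gl$r2, gl$r^2, tolerance = 1e-12)
  # standardized coefficients: coefficient * sd(x) / sd(y)
  expect_equal(m$betas[["age"]],
               coef(m)[["age"]] * sd(tbl$age) / sd(tbl$vo2max),
               tolerance = 1e-12)
})
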