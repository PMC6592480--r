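# Fixture builders shared across the test files. Everything is generated in
# code; no data files.

# minute-indexed trace from raw vectors (NA = non-wear minute)
make_trace <- function(hr, aee, subject_id = "T1",
                       start = "2023-01-09 08:00:00") {
  ts <- as.POSIXct(start, tz = "UTC") + 60 * (seq_along(hr) - 1)
  vo2trace:::new_trace(subject_id, ts, hr, aee)
}

# a trace whose selected minutes lie exactly on aee = slope*hr + intercept:
# one long rising ramp crossing the 120-bpm gate, all within one wear day
make_linear_ramp_trace <- function(slope = 1.2, intercept = -80,
                                   hr_from = 100, hr_to = 180, by = 1,
                                   subject_id = "T1") {
  hr <- seq(hr_from, hr_to, by = by)
  make_trace(hr, slope * hr + intercept, subject_id = subject_id)
}

# small cohort CSV on disk; returns the path
write_cohort_csv <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "cohort.csv")
  writeLines(c(
    "subject_id,age_years,sex,height_cm,weight_kg,percent_body_fat,vo2max_ml_kg_min",
    "S1,27,male,174.3,73.9,20.4,",
    "S2,30,F,161.9,55.8,29.4,35.3",
    "S3,58,male,167.1,67.0,24.2,38.1"
  ), path)
  path
}

# random regression problem for PRESS / model tests
random_design <- function(n, p = 6, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  beta <- rnorm(p + 1)
  y <- beta[1] + X %*% beta[-1] + rnorm(n)
  list(X = X, y = as.numeric(y))
}

# brute-force leave-one-out PRESS: refit the OLS n times
press_brute_force <- function(X, y) {
  n <- length(y)
  sum(vapply(seq_len(n), function(i) {
    df_train <- data.frame(y = y[-i], X[-i, , drop = FALSE])
    fit <- lm(y ~ ., data = df_train)
    pred <- predict(fit, newdata = data.frame(X[i, , drop = FALSE]))
    (y[i] - pred)^2
  }, numeric(1)))
}

# covariate table exactly matching the published worked example
worked_example_covariates <- function(sex = "male") {
  tibble::tibble(aeemax = 141.0, slope = 1.10, percent_body_fat = 20.4,
                 age = 27, sex = sex, height = 174.3)
}

# synthetic modelling table: covariates drawn per stratum, response an exact
# or noisy linear combination of them
make_model_table <- function(n = 60, seed = 1, noise_sd = 0,
                             coefs = coef(vo2trace::published_model())) {
  set.seed(seed)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  tbl <- tibble::tibble(
    sex = sex,
    age = round(runif(n, 20, 65)),
    height = rnorm(n, ifelse(sex == "male", 170, 160), 6),
    percent_body_fat = rnorm(n, ifelse(sex == "male", 23, 32), 5),
    aeemax = rnorm(n, ifelse(sex == "male", 125, 107), 15),
    slope = rnorm(n, 1.0, 0.15)
  )
  tbl$vo2max <- coefs[["constant"]] + coefs[["aeemax"]] * tbl$aeemax +
    coefs[["slope"]] * tbl$slope +
    coefs[["percent_body_fat"]] * tbl$percent_body_fat +
    coefs[["age"]] * tbl$age + coefs[["sex"]] * (tbl$sex == "male") +
    coefs[["height"]] * tbl$height + rnorm(n, 0, noise_sd)
  tbl
}
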