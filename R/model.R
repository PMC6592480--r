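MODEL_TERMS <- c("constant", "aeemax", "slope", "percent_body_fat",
                 "age", "sex", "height")

# internal constructor for the fitted-model container
new_vo2max_model <- function(coefficients, betas, metrics, source,
                             data = NULL, lm_fit = NULL) {
  structure(
    list(coefficients = coefficients, betas = betas, metrics = metrics,
         source = source, data = data, lm = lm_fit),
    class = "vo2max_model"
  )
}

# internal: design matrix (without intercept) in canonical term order;
# sex coded female = 0, male = 1
model_covariates <- function(data) {
  required <- c("aeemax", "slope", "percent_body_fat", "age", "sex", "height")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing model covariate(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "vo2_data_error")
  }
  sex_num <- as.numeric(parse_sex(data$sex) == "male")
  cbind(
    aeemax = as.numeric(data$aeemax),
    slope = as.numeric(data$slope),
    percent_body_fat = as.numeric(data$percent_body_fat),
    age = as.numeric(data$age),
    sex = sex_num,
    height = as.numeric(data$height)
  )
}

#' Fit the nonexercise VO2max regression
#'
#' Ordinary least squares of measured VO2max (mL/kg/min) on the six
#' covariates aEEmax, slope, percent body fat, age, sex (female = 0,
#' male = 1) and height. Reports the Pearson correlation R between measured
#' and fitted values, R², adjusted R², the standard error of estimate
#' SEE = sqrt(SSE/(n − 7)), standardized (beta) coefficients, and the PRESS
#' leave-one-out cross-validated metrics R_P and SEE_P (see [press_cv()]).
#'
#' @param data Tibble with columns `vo2max` (measured, mL/kg/min), `aeemax`,
#'   `slope`, `percent_body_fat`, `age`, `sex`, `height`. Typically a join of
#'   [extract_features()] output with the cohort table.
#' @param see_p_denom `"n"` (default) for SEE_P = sqrt(PRESS/n), `"df"` for
#'   sqrt(PRESS/(n − 7)).
#' @return A `vo2max_model` object; see [tidy.vo2max_model()],
#'   [glance.vo2max_model()], [predict.vo2max_model()].
#' @export
fit_vo2max_model <- function(data, see_p_denom = c("n", "df")) {
  see_p_denom <- match.arg(see_p_denom)
  if (!"vo2max" %in% names(data)) {
    abort("`data` must contain a measured `vo2max` column.",
          class = "vo2_data_error")
  }
  X <- model_covariates(data)
  y <- as.numeric(data$vo2max)
  if (anyNA(X) || anyNA(y)) {
    abort("Model covariates and vo2max must be complete (no NA).",
          class = "vo2_data_error")
  }
  n <- length(y)
  p <- ncol(X) + 1L
  if (n <= p + 1L) {
    abort(sprintf("Need more than %d subjects to fit the model; got %d.",
                  p + 1L, n),
          class = "vo2_data_error")
  }
  Xmat <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(Xmat, y)
  if (fit$rank < p) {
    abort("Design matrix is rank deficient (collinear covariates).",
          class = "vo2_degenerate_error")
  }
  coefs <- setNames(as.numeric(fit$coefficients), MODEL_TERMS)
  yhat <- as.numeric(Xmat %*% fit$coefficients)
  e <- y - yhat
  sse <- sum(e^2)
  ss <- sum((y - mean(y))^2)
  r <- cor(y, yhat)
  see <- sqrt(sse / (n - p))
  betas <- setNames(coefs[-1] * apply(X, 2, sd) / sd(y), MODEL_TERMS[-1])
  cv <- press_cv(X, y, see_p_denom = see_p_denom)
  metrics <- list(
    n = n, r = r, r2 = r^2,
    adj_r2 = 1 - (1 - r^2) * (n - 1) / (n - p),
    see = see, press = cv$press, r_p = cv$r_p, see_p = cv$see_p
  )
  dat <- tibble::as_tibble(data)
  dat$.fitted <- yhat
  dat$.resid <- e
  new_vo2max_model(coefs, betas, metrics, source = "fitted",
                   data = dat, lm_fit = fit)
}

#' The published VO2max estimation model
#'
#' Returns the nonexercise model with its published coefficient vector
#' (constant 63.262; aEEmax 0.027; slope −1.776; percent body fat −0.242;
#' age −0.150; sex 3.264 with female = 0, male = 1; height −0.09), the
#' published standardized coefficients, and the published fit metrics
#' (R 0.807, SEE 3.518 mL/kg/min, R_P 0.787, SEE_P 3.667 mL/kg/min,
#' n = 191) as reported — not recomputed, since the development cohort is
#' not distributed.
#'
#' @return A `vo2max_model` with `source = "published"`.
#' @examples
#' m <- published_model()
#' coef(m)[["constant"]]
#' @export
published_model <- function() {
  coefs <- c(constant = 63.262, aeemax = 0.027, slope = -1.776,
             percent_body_fat = -0.242, age = -0.150, sex = 3.264,
             height = -0.09)
  betas <- c(aeemax = 0.082, slope = -0.045, percent_body_fat = -0.296,
             age = -0.321, sex = 0.548, height = -0.166)
  metrics <- list(n = 191L, r = 0.807, r2 = 0.807^2,
                  adj_r2 = NA_real_, see = 3.518, press = NA_real_,
                  r_p = 0.787, see_p = 3.667)
  new_vo2max_model(coefs, betas, metrics, source = "published")
}

#' @export
coef.vo2max_model <- function(object, ...) object$coefficients

#' Predict VO2max for new subjects
#'
#' Applies the linear model `constant + sum(coefficient × covariate)` with
#' sex coded female = 0, male = 1. Rows with a missing covariate yield `NA`
#' with a warning; a wholly absent covariate column is an error.
#'
#' @param object A `vo2max_model`.
#' @param newdata Tibble with columns `aeemax`, `slope`, `percent_body_fat`,
#'   `age`, `sex`, `height`.
#' @param ... Unused.
#' @return Numeric vector of estimated VO2max, mL/kg/min.
#' @examples
#' predict(published_model(), tibble::tibble(
#'   aeemax = 141, slope = 1.1, percent_body_fat = 20.4,
#'   age = 27, sex = "male", height = 174.3))
#' @export
predict.vo2max_model <- function(object, newdata, ...) {
  X <- model_covariates(newdata)
  if (anyNA(X)) {
    bad <- which(apply(X, 1, anyNA))
    warn(paste0("Missing covariate value(s) for row(s) ",
                paste(bad, collapse = ", "), "; returning NA."),
         class = "vo2_missing_covariate_warning")
  }
  co <- object$coefficients
  as.numeric(co[["constant"]] + X %*% co[MODEL_TERMS[-1]])
}

#' @describeIn fit_vo2max_model Coefficient table: one row per term with the
#'   unstandardized `estimate` and the standardized `beta`.
#' @param x,object A `vo2max_model`.
#' @param ... Unused.
#' @export
tidy.vo2max_model <- function(x, ...) {
  tibble::tibble(
    term = MODEL_TERMS,
    estimate = as.numeric(x$coefficients[MODEL_TERMS]),
    beta = c(NA_real_, as.numeric(x$betas[MODEL_TERMS[-1]]))
  )
}

#' @describeIn fit_vo2max_model One-row metric summary: n, R, R², adjusted
#'   R², SEE, PRESS, R_P, SEE_P.
#' @export
glance.vo2max_model <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(
    n = as.integer(m$n), r = m$r, r2 = m$r2, adj_r2 = m$adj_r2,
    see = m$see, press = m$press %||% NA_real_, r_p = m$r_p, see_p = m$see_p,
    source = x$source
  )
}

#' @export
print.vo2max_model <- function(x, ...) {
  cat(sprintf("Nonexercise VO2max model (%s)\n", x$source))
  print(tidy(x))
  m <- x$metrics
  cat(sprintf("n = %s, R = %.3f, SEE = %.3f, R_P = %.3f, SEE_P = %.3f mL/kg/min\n",
              format(m$n), m$r, m$see, m$r_p, m$see_p))
  invisible(x)
}

#' PRESS leave-one-out cross-validation
#'
#' Computes the predicted residual error sum of squares for the OLS fit of
#' `response` on `design` (with intercept), using the closed form: the
#' leave-one-out residual for case i equals the ordinary residual divided by
#' (1 − leverage_i). Reports the cross-validated correlation
#' R_P = sqrt(max(0, 1 − PRESS/SS)), with SS the total sum of squares of the
#' response about its mean, and SEE_P = sqrt(PRESS/n) (or PRESS/(n − p)
#' with `see_p_denom = "df"`).
#'
#' @param design Numeric covariate matrix or data frame (no intercept
#'   column), one row per case.
#' @param response Numeric response vector.
#' @param see_p_denom `"n"` (default) or `"df"`.
#' @return List with `press`, `r_p`, `see_p`, `loo_residuals`.
#' @export
press_cv <- function(design, response, see_p_denom = c("n", "df")) {
  see_p_denom <- match.arg(see_p_denom)
  X <- cbind(1, as.matrix(design))
  storage.mode(X) <- "double"
  y <- as.numeric(response)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) {
    abort("`design` and `response` sizes disagree.", class = "vo2_data_error")
  }
  if (n <= p) {
    abort("Need more cases than parameters for leave-one-out validation.",
          class = "vo2_data_error")
  }
  qr_x <- qr(X)
  if (qr_x$rank < p) {
    abort("Design matrix is rank deficient (collinear covariates).",
          class = "vo2_degenerate_error")
  }
  beta <- qr.coef(qr_x, y)
  e <- y - as.numeric(X %*% beta)
  Q <- qr.Q(qr_x)
  h <- rowSums(Q^2)
  at_one <- which(1 - h < 1e-10)
  if (length(at_one) > 0) {
    abort(paste0("Leverage equals 1 for case(s) ",
                 paste(at_one, collapse = ", "),
                 "; leave-one-out prediction is undefined."),
          class = "vo2_degenerate_error")
  }
  loo <- e / (1 - h)
  press <- sum(loo^2)
  ss <- sum((y - mean(y))^2)
  r_p <- sqrt(max(0, 1 - press / ss))
  denom <- if (see_p_denom == "n") n else n - p
  list(press = press, r_p = r_p, see_p = sqrt(press / denom),
       loo_residuals = loo)
}

#' Subgroup constant-error validation
#'
#' Splits the cohort by sex, by age (young/old) and by measured VO2max
#' (low/high) and reports, for each subgroup, the constant error
#' CE = mean(measured − estimated) and the SD of the residuals. A CE near
#' zero means the model neither over- nor underestimates that subgroup.
#' Cuts default to the cohort medians (membership: young/low is ≤ cut);
#' override with e.g. `age_cut = 40`, `vo2max_cut = 36` to match a fixed
#' convention.
#'
#' @param model A `vo2max_model`.
#' @param data Tibble with measured `vo2max` plus the six model covariates.
#' @param age_cut Age cut in years (default: cohort median).
#' @param vo2max_cut VO2max cut in mL/kg/min (default: cohort median).
#' @return A tibble of class `vo2_validation`: `split`, `group`, `n`, `ce`,
#'   `sd`, with the cuts stored in the `"cuts"` attribute. Empty subgroups
#'   are reported with `n = 0` and `ce = NA`.
#' @export
subgroup_validation <- function(model, data, age_cut = NULL, vo2max_cut = NULL) {
  if (!"vo2max" %in% names(data) || anyNA(data$vo2max)) {
    abort("Measured `vo2max` must be present for every subject.",
          class = "vo2_data_error")
  }
  est <- predict(model, data)
  resid <- as.numeric(data$vo2max) - est
  age_cut <- age_cut %||% median(as.numeric(data$age))
  vo2max_cut <- vo2max_cut %||% median(as.numeric(data$vo2max))
  sexes <- parse_sex(data$sex)
  groups <- list(
    list(split = "overall", group = "all", mask = rep(TRUE, length(resid))),
    list(split = "sex", group = "female", mask = sexes == "female"),
    list(split = "sex", group = "male", mask = sexes == "male"),
    list(split = "age", group = "young", mask = data$age <= age_cut),
    list(split = "age", group = "old", mask = data$age > age_cut),
    list(split = "vo2max", group = "low", mask = data$vo2max <= vo2max_cut),
    list(split = "vo2max", group = "high", mask = data$vo2max > vo2max_cut)
  )
  out <- purrr::map_dfr(groups, function(g) {
    r <- resid[g$mask]
    tibble::tibble(
      split = g$split, group = g$group, n = length(r),
      ce = if (length(r) > 0) mean(r) else NA_real_,
      sd = if (length(r) > 1) sd(r) else NA_real_
    )
  })
  attr(out, "cuts") <- list(age_cut = age_cut, vo2max_cut = vo2max_cut)
  class(out) <- c("vo2_validation", class(out))
  out
}

#' Pairwise Pearson correlation table
#'
#' Pearson correlations, with two-sided unadjusted p-values, among measured
#' VO2max and the model covariates (sex coded female = 0, male = 1).
#'
#' @param data Tibble containing the requested columns.
#' @param vars Columns to correlate; defaults to the model's variable set.
#' @return Long tibble `var1`, `var2`, `r`, `p_value`, `n` for every
#'   unordered pair (`var1` before `var2` in `vars` order). Zero-variance
#'   columns yield `NA` with a warning.
#' @export
correlation_table <- function(data,
                              vars = c("vo2max", "age", "height", "sex",
                                       "percent_body_fat", "aeemax", "slope")) {
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "vo2_data_error")
  }
  df <- data[vars]
  if ("sex" %in% vars) df$sex <- as.numeric(parse_sex(df$sex) == "male")
  df <- as.data.frame(lapply(df, as.numeric))
  if (nrow(df) < 3) {
    abort("Need at least 3 subjects for a correlation table.",
          class = "vo2_data_error")
  }
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    x <- df[[pr[1]]]
    y <- df[[pr[2]]]
    ok <- !is.na(x) & !is.na(y)
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      warn(sprintf("Zero variance in %s/%s; correlation undefined.",
                   pr[1], pr[2]))
      return(tibble::tibble(var1 = pr[1], var2 = pr[2], r = NA_real_,
                            p_value = NA_real_, n = sum(ok)))
    }
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    tibble::tibble(var1 = pr[1], var2 = pr[2],
                   r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
  })
}
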