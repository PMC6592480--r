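#' Read a minute-level activity trace
#'
#' Parses a trace CSV as produced by a watch-type fitness tracker export:
#' one row per minute with columns `timestamp` (ISO 8601), `hr_bpm`
#' (heart rate, beats/min) and `aee_kcal_kg_h` (activity energy expenditure,
#' kcal/kg/h, a MET-like quantity). Minutes where either measurement is
#' missing are retained with `wear = FALSE`; nothing is ever imputed.
#'
#' @param path Path to the trace CSV.
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension, or the file's `subject_id` column when present.
#' @return A tibble of class `vo2_trace` with columns `subject_id`,
#'   `timestamp` (POSIXct, strictly increasing), `hr`, `aee` and the logical
#'   `wear` (TRUE iff both `hr` and `aee` are present that minute).
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "timestamp,hr_bpm,aee_kcal_kg_h",
#'   "2023-01-09T08:00:00Z,70,1.0",
#'   "2023-01-09T08:01:00Z,72,1.2"
#' ), path)
#' read_trace(path)
#' @export
read_trace <- function(path, subject_id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("Trace file not found: ", path), class = "vo2_io_error")
  }
  raw <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_guess()),
                    progress = FALSE, show_col_types = FALSE),
    error = function(e) abort(paste0("Cannot parse trace CSV: ", conditionMessage(e)),
                              class = "vo2_format_error")
  )
  required <- c("timestamp", "hr_bpm", "aee_kcal_kg_h")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Trace CSV is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "vo2_format_error")
  }
  if (anyDuplicated(names(raw))) {
    abort("Trace CSV has duplicated column names.", class = "vo2_format_error")
  }
  if (nrow(raw) == 0) {
    abort("Trace CSV contains no rows.", class = "vo2_data_error")
  }
  ts <- raw$timestamp
  if (!inherits(ts, "POSIXct")) {
    ts <- as.POSIXct(as.character(ts), tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                    "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M"))
  }
  if (anyNA(ts)) {
    abort("Trace timestamps could not be parsed as ISO 8601.",
          class = "vo2_format_error")
  }
  if (any(diff(as.numeric(ts)) <= 0)) {
    abort("Trace timestamps must be strictly increasing.",
          class = "vo2_data_error")
  }
  hr <- as.numeric(raw$hr_bpm)
  aee <- as.numeric(raw$aee_kcal_kg_h)
  if (any(hr <= 0, na.rm = TRUE)) {
    abort("Heart rate must be positive where present.", class = "vo2_data_error")
  }
  if (any(aee < 0, na.rm = TRUE)) {
    abort("Activity energy expenditure must be nonnegative where present.",
          class = "vo2_data_error")
  }
  sid <- subject_id %||%
    (if ("subject_id" %in% names(raw)) as.character(raw$subject_id[[1]])
     else sub("\\.[^.]*$", "", basename(path)))
  new_trace(sid, ts, hr, aee)
}

# internal constructor enforcing the trace invariants
new_trace <- function(subject_id, timestamp, hr, aee) {
  stopifnot(length(timestamp) == length(hr), length(hr) == length(aee))
  out <- tibble::tibble(
    subject_id = as.character(subject_id),
    timestamp = timestamp,
    hr = as.numeric(hr),
    aee = as.numeric(aee),
    wear = !is.na(hr) & !is.na(aee)
  )
  class(out) <- c("vo2_trace", class(out))
  out
}

#' Write a trace to CSV
#'
#' Inverse of [read_trace()]: writes `timestamp,hr_bpm,aee_kcal_kg_h`
#' (plus `subject_id`) so that reading the file back reproduces the trace.
#'
#' @param trace A `vo2_trace` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  out <- tibble::tibble(
    subject_id = trace$subject_id,
    timestamp = format(trace$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    hr_bpm = trace$hr,
    aee_kcal_kg_h = trace$aee
  )
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a cohort metadata table
#'
#' Parses a cohort CSV with one row per subject and columns
#' `subject_id,age_years,sex,height_cm,weight_kg,percent_body_fat,vo2max_ml_kg_min`.
#' Sex tokens are parsed case-insensitively: female/f/0 and male/m/1.
#' `weight_kg` and `vo2max_ml_kg_min` may be blank (weight is not a model
#' covariate; measured VO2max is only needed for fitting and validation).
#'
#' @param path Path to the cohort CSV.
#' @param check_plausibility Warn (never fail) when age, height or percent
#'   body fat fall outside broad plausibility bounds.
#' @return A tibble of class `vo2_cohort` with columns `subject_id`, `age`,
#'   `sex` ("female"/"male"), `height`, `weight`, `percent_body_fat`,
#'   `vo2max` (NA when not measured).
#' @export
read_cohort <- function(path, check_plausibility = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("Cohort file not found: ", path), class = "vo2_io_error")
  }
  raw <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(
      subject_id = readr::col_character(),
      sex = readr::col_character(),
      .default = readr::col_double()
    ), progress = FALSE, show_col_types = FALSE),
    error = function(e) abort(paste0("Cannot parse cohort CSV: ", conditionMessage(e)),
                              class = "vo2_format_error")
  )
  required <- c("subject_id", "age_years", "sex", "height_cm",
                "percent_body_fat")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort CSV is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "vo2_format_error")
  }
  if (nrow(raw) == 0) {
    abort("Cohort CSV contains no rows.", class = "vo2_data_error")
  }
  if (anyDuplicated(raw$subject_id)) {
    dup <- unique(raw$subject_id[duplicated(raw$subject_id)])
    abort(paste0("Duplicate subject_id in cohort: ",
                 paste(dup, collapse = ", ")),
          class = "vo2_format_error")
  }
  out <- tibble::tibble(
    subject_id = raw$subject_id,
    age = as.numeric(raw$age_years),
    sex = parse_sex(raw$sex),
    height = as.numeric(raw$height_cm),
    weight = if ("weight_kg" %in% names(raw)) as.numeric(raw$weight_kg) else NA_real_,
    percent_body_fat = as.numeric(raw$percent_body_fat),
    vo2max = if ("vo2max_ml_kg_min" %in% names(raw))
      as.numeric(raw$vo2max_ml_kg_min) else NA_real_
  )
  if (check_plausibility) {
    flag <- function(cond, what) {
      bad <- which(cond)
      if (length(bad) > 0) {
        warn(paste0("Implausible ", what, " for subject(s): ",
                    paste(out$subject_id[bad], collapse = ", ")))
      }
    }
    flag(!is.na(out$age) & (out$age < 18 | out$age > 90), "age")
    flag(!is.na(out$height) & (out$height < 120 | out$height > 220), "height")
    flag(!is.na(out$percent_body_fat) &
           (out$percent_body_fat <= 0 | out$percent_body_fat >= 100),
         "percent body fat")
  }
  class(out) <- c("vo2_cohort", class(out))
  out
}

# internal: case-insensitive sex token parsing
parse_sex <- function(x) {
  tok <- tolower(trimws(as.character(x)))
  out <- dplyr::case_when(
    tok %in% c("female", "f", "0") ~ "female",
    tok %in% c("male", "m", "1") ~ "male",
    TRUE ~ NA_character_
  )
  if (anyNA(out)) {
    bad <- unique(tok[is.na(out)])
    abort(paste0("Unparseable sex token(s): ", paste(bad, collapse = ", "),
                 " (expected female/f/0 or male/m/1)"),
          class = "vo2_format_error")
  }
  out
}

#' Write a cohort table to CSV
#'
#' @param cohort A `vo2_cohort` tibble (see [read_cohort()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- tibble::tibble(
    subject_id = cohort$subject_id,
    age_years = cohort$age,
    sex = cohort$sex,
    height_cm = cohort$height,
    weight_kg = cohort$weight,
    percent_body_fat = cohort$percent_body_fat,
    vo2max_ml_kg_min = cohort$vo2max
  )
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write per-subject features to CSV
#'
#' One row per subject with the columns
#' `subject_id,hrmax_bpm,slope_kcal_kg_h_per_bpm,intercept_kcal_kg_h,aeemax_kcal_kg_h,n_points`
#' plus diagnostics (`pearson_r_fit`, `n_wear_minutes`, `low_aeemax_flag`).
#'
#' @param features A feature tibble from [extract_features()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  out <- tibble::tibble(
    subject_id = features$subject_id,
    hrmax_bpm = features$hrmax,
    slope_kcal_kg_h_per_bpm = features$slope,
    intercept_kcal_kg_h = features$intercept,
    aeemax_kcal_kg_h = features$aeemax,
    n_points = features$n_points,
    pearson_r_fit = features$pearson_r_fit,
    n_wear_minutes = features$n_wear_minutes,
    low_aeemax_flag = features$low_aeemax_flag
  )
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a per-subject features CSV
#'
#' Inverse of [write_features()].
#'
#' @param path Path to a features CSV.
#' @return A feature tibble with the same columns as [extract_features()].
#' @export
read_features <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Features file not found: ", path), class = "vo2_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("subject_id", "hrmax_bpm", "slope_kcal_kg_h_per_bpm",
                "intercept_kcal_kg_h", "aeemax_kcal_kg_h", "n_points")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Features CSV is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "vo2_format_error")
  }
  tibble::tibble(
    subject_id = as.character(raw$subject_id),
    hrmax = raw$hrmax_bpm,
    slope = raw$slope_kcal_kg_h_per_bpm,
    intercept = raw$intercept_kcal_kg_h,
    aeemax = raw$aeemax_kcal_kg_h,
    n_points = as.integer(raw$n_points),
    pearson_r_fit = if ("pearson_r_fit" %in% names(raw)) raw$pearson_r_fit else NA_real_,
    n_wear_minutes = if ("n_wear_minutes" %in% names(raw))
      as.integer(raw$n_wear_minutes) else NA_integer_,
    low_aeemax_flag = if ("low_aeemax_flag" %in% names(raw))
      as.logical(raw$low_aeemax_flag) else NA
  )
}

#' Write a fitted model to JSON
#'
#' Serializes coefficients (key order `constant,aeemax,slope,percent_body_fat,
#' age,sex,height`), standardized coefficients and fit/cross-validation
#' metrics at full numeric precision, so that [read_model()] reproduces the
#' model exactly.
#'
#' @param model A `vo2max_model` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  payload <- list(
    type = "vo2max_model",
    source = model$source,
    coefficients = as.list(model$coefficients),
    betas = as.list(model$betas),
    metrics = model$metrics
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path Path to a JSON file produced by [write_model()].
#' @return A `vo2max_model` object.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Model file not found: ", path), class = "vo2_io_error")
  }
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                      error = function(e)
                        abort(paste0("Cannot parse model JSON: ",
                                     conditionMessage(e)),
                              class = "vo2_format_error"))
  if (!identical(payload$type, "vo2max_model") ||
      is.null(payload$coefficients)) {
    abort("Not a vo2max model JSON file.", class = "vo2_format_error")
  }
  coefs <- unlist(payload$coefficients)
  expected <- c("constant", "aeemax", "slope", "percent_body_fat",
                "age", "sex", "height")
  if (!identical(sort(names(coefs)), sort(expected))) {
    abort("Model JSON must carry exactly the coefficients: constant, aeemax, slope, percent_body_fat, age, sex, height.",
          class = "vo2_format_error")
  }
  metrics <- lapply(payload$metrics, function(v) if (is.null(v)) NA_real_ else v)
  new_vo2max_model(
    coefficients = coefs[expected],
    betas = unlist(payload$betas),
    metrics = metrics,
    source = payload$source %||% "file"
  )
}

#' Write a subgroup validation report to JSON
#'
#' @param report A `vo2_validation` tibble from [subgroup_validation()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  payload <- list(
    type = "vo2max_validation",
    cuts = attr(report, "cuts"),
    groups = purrr::pmap(report, function(split, group, n, ce, sd) {
      list(split = split, group = group, n = n, ce = ce, sd = sd)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
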