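Package: vo2trace
Title: Estimate Maximal Oxygen Uptake from Wrist-Tracker Activity Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates cardiorespiratory fitness (maximal oxygen uptake,
    VO2max) from minute-level heart-rate and activity-energy-expenditure
    traces recorded by watch-type fitness trackers. Implements the signal
    processing chain (moving-average smoothing, co-increase minute
    selection, a 120 beats/min heart-rate gate), extraction of the two
    trace-derived fitness features (the heart-rate to activity slope and
    the maximal activity energy expenditure aEEmax), a nonexercise
    multiple linear regression for VO2max with PRESS leave-one-out
    cross-validation and subgroup constant-error validation, and a
    seed-deterministic synthetic cohort and trace simulator with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
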