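---
title: "Methods: nonexercise VO2max estimation from wrist-tracker traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nonexercise VO2max estimation from wrist-tracker traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(vo2trace)
library(dplyr)
```

## The estimation problem

Maximal oxygen uptake (VO₂max, mL/kg/min) is the criterion measure of
cardiorespiratory fitness, but measuring it requires a maximal graded
exercise test with gas analysis. Nonexercise estimation replaces the test
with quantities obtainable from daily life. This package implements an
estimator whose inputs are (a) a few days of minute-resolution heart rate
(HR, beats/min) and activity energy expenditure (aEE, kcal/kg/h — a
MET-like quantity, 1 kcal/kg/h at rest) from a wrist-worn tracker, and (b)
basic anthropometrics: age, sex, height, percent body fat.

The physiological premise is that for exertion above moderate intensity, a
subject's aEE rises approximately linearly with HR, and the parameters of
that line index fitness: a fitter subject produces more external activity
per heartbeat and would reach a higher activity level at maximal heart
rate (the two line parameters act jointly as covariates in the VO₂max
regression rather than as standalone fitness scores). Two features
summarise the line:

* **slope** — the OLS coefficient of aEE on HR (kcal/kg/h per beat/min);
* **aEEmax** — the fitted line evaluated at the age-predicted maximal heart
  rate: `aEEmax = slope · HRmax + intercept` (kcal/kg/h).

The regression is deliberately run with aEE as the response: aEEmax is
defined as an *activity* value at a given heart rate, and the slope's units
(kcal/kg/h per bpm) follow from that orientation.

## The signal-processing chain

`extract_features()` applies, in order:

1. **Sufficiency check.** At least `min_wear_minutes` (default 900 = 15 h)
   of wear time — minutes with both channels present — are required, and a
   span under `min_days` (default 3) calendar days warns without failing.
   The 15-hour floor is interpreted as *total wear time*, not
   post-selection activity time; both the floor and the interpretation are
   configurable.
2. **Smoothing.** A centred moving average (`smooth_window_min`, default
   5 min) is applied to both channels independently within each contiguous
   wear segment; windows never span a non-wear gap, shrink at segment
   edges, and missing minutes stay missing. Five minutes is short enough to
   preserve activity bouts at 1-minute sampling while attenuating
   single-minute sensor jitter. Nothing is ever imputed: the device is
   removed during sleep and showering, and only collected data are used.
3. **Co-increase selection.** First differences of both smoothed series are
   taken within wear segments; a minute is kept when *both* differences are
   strictly positive (the kept minute is the later endpoint of the step).
   This isolates periods of ramping physical activity, where the HR–aEE
   coupling is informative, and discards recovery periods, where HR decays
   on its own schedule.
4. **Heart-rate gate.** Of the co-increase minutes, only those with
   smoothed HR strictly greater than `hr_gate_bpm` (default 120) are kept,
   excluding the low-intensity region where HR and aEE are nonlinearly
   related. Both the co-increase test and the gate are strict
   inequalities.
5. **Per-subject regression.** OLS of smoothed aEE on smoothed HR over the
   selected minutes (at least `min_points`, default 30 — a stability floor
   for a two-parameter fit, chosen as a package convention). Smoothed
   values, not raw ones, enter the regression, matching the chain order
   (filter first, then select).
6. **HRmax and aEEmax.** HRmax = 200 − 0.67·age (women) or 216 − 0.93·age
   (men), applied without rounding; the four constants are configurable as
   a single override point. aEEmax is the line at HRmax. An aEEmax below
   the 1 kcal/kg/h resting level is physiologically implausible; it is
   flagged (`low_aeemax_flag`) but never silently dropped.

Two ordering points were genuinely open and are fixed here as package
conventions: the gate is applied *after* the co-increase selection (the
narrative order of the chain), and the per-subject regression pools all
days rather than fitting per day.

## The VO2max model

`fit_vo2max_model()` fits
`vo2max ~ aeemax + slope + percent_body_fat + age + sex + height`
by OLS, with sex coded female = 0, male = 1 (the coded covariate must be 1
for males for a positive sex coefficient to raise male estimates, as the
published +3.264 does). Reported metrics:

* `r` — Pearson correlation of measured vs fitted; `r2 = r²`. Both the
  plain and the adjusted R² are reported and labelled explicitly, because
  the two are easily conflated when quoted side by side.
* `see = sqrt(SSE / (n − 7))` — standard error of estimate on the residual
  degrees of freedom of the 6-covariate-plus-intercept model. No formula is
  mandated by convention-free inputs; this is the standard choice.
* PRESS cross-validation (`press_cv()`): the leave-one-out residual for
  case *i* is `e_i / (1 − h_i)` with `h_i` the hat-matrix leverage, so the
  full PRESS needs a single fit. `r_p = sqrt(max(0, 1 − PRESS/SS))` with SS
  the total sum of squares of the response. `see_p = sqrt(PRESS / n)` by
  default; the denominator is configurable to `n − 7` (`see_p_denom =
  "df"`) because the defining convention is not uniquely fixed in the
  literature this estimator follows. Since every leave-one-out residual
  dominates its in-sample residual (leverages lie in [0, 1)),
  `PRESS ≥ SSE`, hence `r_p ≤ r`; a leverage of exactly 1 makes the
  leave-one-out prediction undefined and is refused with the offending
  case named.
* `published_model()` returns the fixed published coefficient vector with
  its metrics *as reported* — they are statistics of the 191-subject
  development cohort, which is not distributed, so nothing is recomputed.

`subgroup_validation()` reports the constant error CE = mean(measured −
estimated) and residual SD by sex, age (young/old) and measured VO₂max
(low/high). The sign convention (measured − estimated) makes CE positive
when the model underestimates. Cuts default to the cohort medians, with
fixed overrides (e.g. 40 years, 36 mL/kg/min) available; membership is
young/low ≤ cut. Two CE facts are structural for an OLS fit evaluated on
its own training data: the overall CE is zero, and the CE within each
level of any categorical covariate included in the model (sex) is zero to
machine precision — residuals are orthogonal to every design column. The
fitness split instead shows regression to the mean: positive CE in the
high group, negative in the low group.

## The synthetic study generator

No subject data are distributed, so the simulator is the package's test
bed; it is first-class, tested code.

`simulate_cohort()` draws subjects in six strata (sex × age band 20–35 /
36–50 / 51–65) from normal distributions truncated at ±3 SD (to avoid
physiologically absurd subjects while keeping moments near-normal), using
the development cohort's published stratum means/SDs for height, weight,
percent fat, aEEmax and slope, and the published stratum sizes (total
n = 191) by default. Each subject's true line intercept is implied:
`intercept = aEEmax − slope · HRmax`. Measured VO₂max is generated as the
published coefficient vector applied to the covariates plus Gaussian noise
(SD 3.5 mL/kg/min, matching the scale of the published SEE), so the
generative coefficients are known and parameter recovery can be tested.

`simulate_trace()` builds each day as a 14-hour wear window (08:00–22:00;
the device is off overnight — non-wear gaps are real missing data) with a
resting baseline (HR 70 bpm, aEE 1 kcal/kg/h) interrupted by 5 activity
bouts. Bouts ramp HR up at 2 bpm/min to a peak of
`120 + f·(HRmax − 120)` with `f` cycling {0.35, 0.55, 0.75, 0.90, 0.99}
(so bouts reach high fractions of the subject's aEEmax), hold 2 minutes,
and descend at twice the ramp rate. The clean activity response is exactly
`slope·HR + intercept` at or above `linear_break_bpm` = 110, and below it a
continuous quadratic curve flattening to the resting level — the
low-intensity nonlinearity that motivates the 120-bpm gate. Independent
Gaussian noise (default SD 2 bpm and 2 kcal/kg/h) is added to both
channels; minute-level tracker output is already internally averaged from
high-rate sensing, so its residual minute-to-minute jitter is small.

Two numerical design points deserve emphasis:

* **Breakpoint below the gate.** The linear regime starts at 110 bpm, 10
  bpm below the gate, and ramp rates are capped at 5 bpm/min. A centred
  5-minute window around any minute whose *smoothed* HR clears 120 then
  contains only raw minutes ≥ 110 bpm, i.e. only linear-regime samples —
  and a moving average commutes with an affine response, so with zero noise
  the selected smoothed points lie *exactly* on the true line and the
  whole chain inverts to machine precision. Had the nonlinearity run right
  up to 120 bpm, smoothing would mix regimes near the gate and exact
  recovery would be impossible by construction. The gate still matters:
  the co-increase step alone admits sub-110 minutes whose response is
  nonlinear, so skipping the gate biases the fit.
* **Noise and design strength.** Defaults were fixed once from a power
  analysis of the per-subject regression: with ~200–400 selected minutes
  spanning 120 bpm to near HRmax, the sampling error of the slope and of
  aEEmax (an interpolation near the data's upper range) is well under 5 %.
  The line's *intercept*, by contrast, is an extrapolation to HR = 0, far
  outside the supported range, and its relative error is intrinsically
  several-fold larger — which is why recovery guarantees are stated for
  slope and aEEmax under noise, and for all three parameters only in the
  noiseless limit.

What the simulator does **not** model: device-specific bias (the feature
construction is trend-based precisely to absorb it, so a constant bias
would cancel in differences), circadian HR structure beyond the day/night
wear cycle, empirical bout intensity/duration distributions (the bout
schedule is a package convention), HR artefacts, and correlation between
covariates *within* a stratum (covariates are drawn independently around
stratum means, so cross-covariate correlations arise only from stratum
structure). Consequently, passing tests demonstrate that the chain is
correct and well-conditioned under its stated assumptions — not that
real-tracker accuracy matches any particular figure; whole-cohort
correlation metrics on simulated cohorts are expected to differ from those
of the real development cohort.

Determinism: every generator takes an explicit seed; per-subject trace
seeds are drawn once from the cohort seed, so identical configuration plus
seed reproduce a study bit-for-bit.

## Problem sizes in the test suite

The suite exercises: PRESS closed form vs an explicit refit-n-times oracle
on 100 random designs of n = 12–50 with 6 covariates; feature recovery on
100 single-subject seeds at default noise (and exact recovery at zero
noise); coefficient recovery on 100 simulated cohorts of n = 191; and an
end-to-end simulate → extract → fit → validate run. These sizes keep the
default suite under a minute while leaving each check statistically sharp.

## Known limitations

* HRmax comes from population age formulas; individual deviation
  propagates directly into aEEmax.
* The estimator assumes above-gate linearity of the HR–aEE response; data
  from subjects on chronotropic medication violate it.
* Subjects whose traces never exceed 120 bpm yield no regression points
  and are excluded (reported, not silently dropped) — the method needs at
  least some vigorous daily activity.
* The published model's metrics are carried as reported; they cannot be
  audited without the original cohort.
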