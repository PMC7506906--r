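---
title: "Predicting balance ability from an instrumented Timed Up and Go: methods"
author: "itug package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting balance ability from an instrumented Timed Up and Go: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The Community Balance and Mobility Scale (CBMS, 0–96 points, higher =
better) is a comprehensive performance-based assessment of balance and
mobility in seniors, but it takes 20–25 minutes, floor space and trained
assessors. The Timed Up and Go (TUG) — stand from a chair, walk 3 m
around a cone, walk back, turn and sit down — takes under a minute and
only a chair and a cone. When the TUG is *instrumented* (iTUG) with the
inertial sensors of a smartphone worn on the lower back, each repetition
yields a rich set of temporal, intensity and smoothness features, and
the question becomes statistical: how much of the CBMS score can a
regression on those features recover, and does it beat the standard
clinical tests (TUG stopwatch time, gait speeds, SPPB, 30-second chair
stand, eight-level balance scale, short FES-I)?

This package implements that analysis end to end: IMU log ingestion,
phase segmentation, a 78-feature catalogue averaged over five TUG
repetitions, and a single-response partial least squares regression
(PLS1) validated by Monte-Carlo cross-validation with feature screening
inside the loop, plus a calibrated synthetic cohort generator so that
every stage is testable against known ground truth without access to
clinical data.

## Pipeline

```{r}
library(itug)
res <- run_pipeline(run_config(n_community = 40, n_outpatient = 20,
                               seed = 7))
run_report(res$out_dir)
```

The stages, each exposed as ordinary functions:

1. **Ingestion** (`read_imu_log`, `resample_recording`, `align_axes`).
   Logs are plain text, `t_ns ax ay az gx gy gz` (nanosecond timestamps,
   m/s², deg/s), resampled by linear interpolation from the device's
   nominal ~102.5 Hz onto a uniform 100 Hz grid. Linear interpolation is
   adequate because voluntary movement content lies well below 5 Hz and
   the target rate nearly equals the source rate; no anti-alias filter
   is applied. A signed axis permutation maps device axes onto the
   anatomical frame (AP, ML, V); synthetic data is generated directly in
   anatomical axes, so its map is the identity.
2. **Segmentation** (`split_repetitions`, `segment_trial`). A session of
   five repetitions separated by 30 s rests is split on gyro activity,
   then each repetition is segmented into Sit-to-Walk (StW), walk-out
   (W1), First Turn (FT), walk-back (W2) and Turn-to-Sit (TtS, which
   contains a turning sub-interval and the sit-down). Turns come from
   the yaw angular velocity, transitions from the pitch angular velocity
   and AP acceleration (details below).
3. **Features** (`extract_features`, `average_features`). 78 signal
   features per repetition — the catalogue in `feature_manifest()` —
   averaged across the five repetitions, then joined with subject
   descriptives (age, education, sex, height, weight, BMI).
4. **Regression and validation** (`fit_pls1`, `monte_carlo_cv`,
   `compare_models`). Two predictor models against the same CBMS
   response: model 1 = descriptives + iTUG features, model 2 =
   descriptives + clinical tests; their cross-validated prediction
   errors are compared as a paired sample over shared partitions.

## Segmentation rules and thresholds

The segmentation literature for trunk-worn sensors offers a family of
threshold rules rather than one canonical algorithm; the ones used here
are conventional and all exposed in `seg_config()`:

* **Turns**: yaw angular velocity, zero-phase low-pass at 1.5 Hz,
  median-detrended. Excursions beyond 45 deg/s seed candidates, each
  extended outward to the nearest crossing of max(5 deg/s, 10% of that
  candidate's peak), merged when overlapping, and retained when the
  integrated angle reaches 90 deg. A valid repetition has exactly two
  such turns (~180 deg each); any other count is a segmentation failure
  carrying the count found.
* **Transitions**: stand-up onset and sit-down end are the earliest and
  latest sustained (0.2 s) exceedances of 3x the quiescent-baseline SD
  on the low-passed ML angular velocity or mean-subtracted AP
  acceleration. Transitions use a wider 5 Hz filter than turns: a
  zero-phase 1.5 Hz filter smears the brief stand-up pulse backwards by
  several tenths of a second and would bias the onset early. A relative
  floor (2% of the channel peak) keeps the threshold meaningful when
  recordings are noise-free. A recording whose first second is not quiet
  relative to its most active stretch has no usable baseline and errors.
* **Phases**: StW runs from the onset to the first detected step; W1 to
  the first turn; W2 between the turns; TtS from the second turn's start
  to the sit-down end. All intervals are half-open `[start, end)`
  seconds. The StW/W1 boundary is tied to the first footfall because
  sit-to-walk ends when gait begins.
* **Session splitting** uses the sum over axes of a 1 s moving SD of the
  6 Hz low-passed gyro, threshold 8 deg/s, gaps of at least 5 s
  separating repetitions. The sum of per-axis SDs rather than the SD of
  the magnitude matters: during steady gait the ML and yaw oscillations
  are in phase quadrature, leaving the magnitude nearly constant — the
  magnitude-SD statistic goes blind exactly when the subject walks
  slowly and steadily.

## The feature catalogue

`feature_manifest()` enumerates all 78 features: durations of every
phase and sub-interval (9), RMS of acceleration and of angular velocity
per axis over StW/W/FT/TtS/total (30), angular-velocity ranges over the
same grid (15) and acceleration ranges over the walk (3), normalized
jerk scores of acceleration over the walk and StW (6), normalized
angular jerk scores of the two turns (2), mean and peak turning
velocity for both turns (4), step counts (4), average step length, gait
speed and cadence (3), and step regularity on V and AP (2).

Conventions worth stating:

* **RMS** uses mean-subtracted acceleration (removing the gravity
  component and constant bias) and raw angular velocity.
* **Normalized jerk score (NJS)**:
  `NJS = sqrt(T^5 / (2 A^2) * integral j(t)^2 dt)` with `j` the central
  difference of acceleration, `T` the interval duration, and `A` the
  displacement amplitude obtained by twice integrating the
  mean-subtracted acceleration. Mean subtraction (rather than removing
  a fitted linear trend) is deliberate: a minimum-jerk acceleration
  pulse itself has a nonzero linear regression component, so linear
  detrending would distort the very profile the score is normalized
  against, while mean subtraction leaves it intact and still removes
  constant sensor bias. A minimum-jerk movement scores `sqrt(360)`
  (~18.97) regardless of duration or amplitude; the tests hold the
  implementation to that closed form within 2% at 100 Hz. The angular
  version (NAJS) differentiates angular velocity twice and normalizes
  by the integrated angle.
* **Steps** are local maxima of band-passed (0.5–3 Hz) vertical
  acceleration with prominence at least 0.3 m/s² and 0.3 s separation;
  the analysis window is padded by one separation so footfalls on phase
  boundaries are not lost. **Gait speed** is the nominal 6 m round trip
  over the summed walking-leg durations (the protocol fixes the cone at
  3 m; the walked distance is not estimated from the signals), step
  length is 6 m per step, cadence is steps per second.
* **Step regularity** is the unbiased autocorrelation of mean-subtracted
  acceleration at the dominant step period, as a percentage of lag 0,
  pooled across the two walking legs (each leg alone can hold fewer
  than four steps at fast gait, which is too short for a lone
  autocorrelation estimate).
* Kinematic and smoothness features are computed on lightly smoothed
  channels (6 Hz for angular velocity, 10 Hz for acceleration,
  zero-phase) so that broadband sensor noise does not dominate
  derivatives; RMS/range features use the unsmoothed signals.

A feature whose computation fails on a repetition becomes `NA` with the
reason recorded; a repetition missing more than 20% of features is an
error, and averaging across repetitions ignores missing values.

## The regression engine

`fit_pls1` is NIPALS for a single response: predictors are z-scored —
required for VIP comparability because the catalogue mixes deg/s,
seconds, steps and percent — and the response is centred (scaling the
response would change nothing: predictions and coefficients on the
original scale are invariant to it). Per component `a`: weights
`w_a` proportional to `X_a' y_a` normalized to unit length, scores
`t_a = X_a w_a`, loadings `p_a`, response loading `q_a`, then deflation
of both matrices. Coefficients for any component count are recovered
through `W (P'W)^{-1} q`. Scores are mutually orthogonal and the
cumulative explained variation is non-decreasing and bounded by 1; at
full rank the fit equals ordinary least squares — both properties are
tested, and the whole engine is checked against an independent PLS
implementation (mixOmics) to 1e-6 on random tables.

**VIP** uses the standard formula
`VIP_j = sqrt(m * sum_a ssy_a w_ja^2 / sum_a ssy_a)`, whose squared
values average to exactly 1 across features; classification against the
conventional 0.83 / 1 / 1.21 cut-offs assigns boundary values upward.

## Monte-Carlo cross-validation

Each of 100 iterations repartitions the subjects at random into six
near-equal sets, trains on five and tests on one. Feature screening —
keep features whose Pearson correlation with the training response has
p < 0.05 — runs *inside* the loop on training rows only; running it
once on all data before splitting is the classic leakage error this
design exists to avoid, and the test suite checks the guard by feeding
a permuted response (60 x 78 pure-noise table) and requiring the pooled
predicted-vs-measured R² to stay within ±0.1 of zero.

Reported accuracy comes in two forms: the pooled chemometrics
`Q² = 1 − ΣPRESS/ΣTSS`, and `test_r2`, the squared correlation between
pooled held-out predictions and observed responses (the
predicted-vs-measured scatter accuracy). Averaging per-iteration R²
values over 10-subject test folds is deliberately avoided — the ratio
of two small-sample quantities has a Jensen-type negative bias of
about −0.1 to −0.2 even for a perfectly sound procedure.

**Component choice** follows a one-standard-error parsimony rule: the
candidate counts are those whose mean RMSEP lies within
`SD_min/sqrt(n_iter)` of the minimum mean, and the smallest candidate
wins. The raw SD across iterations is dominated by test-fold sampling
noise — typically an order of magnitude wider than the differences
between adjacent counts — and using it as the tolerance collapses every
curve to one or two components; the standard error expresses
"statistically indistinguishable from the minimum", which is the
convention of keeping the smaller model when a larger one is only
insignificantly better (e.g. retaining 3 components over a 4th whose
improvement has p = 0.9).

The final reported feature set contains the features selected in more
than half the iterations (threshold exposed in `cv_config`); the final
model is refitted on all subjects restricted to that set, at the chosen
component count. Explained variation per component is aggregated across
the iterations' training fits with percentile 95% confidence intervals.
If no feature is stably selected (a null response), the final model
falls back to the two most frequent features with a warning rather than
failing, so the diagnostic quantities remain available.

**Model comparison** is a paired Z-test: both models are validated with
the same master seed, hence identical partitions, and the per-iteration
RMSEP values (each at its model's chosen component count) form matched
pairs; `Z = mean(d)/(SD(d)/sqrt(n_iter))` with a two-sided normal
p-value, and a model compared with itself returns Z = 0, p = 1 by
convention. Pairing is the valid design here because the same subjects
and folds underlie both models. All randomness flows from one master
seed through per-iteration substreams, so any run is exactly
reproducible and two models are comparable fold by fold.

## The synthetic cohort generator

No sensor recordings are distributed with the study this design
emulates, so the package ships a generator whose defaults encode the
study conditions: 40 community-dwelling seniors and 20 geriatric
outpatients, five repetitions each with 30 s rests, a 3 m cone
distance, ~180 deg turns.

**Latent structure.** Each subject draws a dominant ability factor
(cohort-specific Gaussians on a common standardized scale) plus two
minor factors — turn-specific and transition-specific. CBMS responds to
all three (weights 1 : 0.30 : 0.25 before standardization); clinical
test scores respond to overall ability only; the turning velocity and
the transition durations draw on their respective minor factors. This
gives the cross-validated regression genuinely multi-component
structure, and it is why the iTUG model outperforms the clinical model
in the demo pipeline: part of the balance-relevant variance is visible
only in the movement signals.

**Calibration.** Every clinical variable is generated as a clamped
(and, for integer scales, rounded) Gaussian linked to the latent
ability with a variable-specific correlation. The pre-clamp mean and SD
are solved numerically (moment matching of the clamped normal) so that
the *post-clamp* sample moments reproduce the published cohort
characteristics; this matters for heavily censored scales — the
outpatient CBMS piles probability at 0, the community SPPB at 12, and
naive parameter choices would miss the target means by far more than a
standard error. `cohort_reference_table()` lists all targets; the
acceptance script re-simulates 4000-subject cohorts and reports the
sample means of CBMS (both cohorts), community habitual gait speed and
outpatient TUG time.

**Signals.** A trial is assembled from phases: quiet sitting;
Sit-to-Walk as a minimum-jerk forward acceleration pulse plus a pitch
angular-velocity pulse; walking legs with step oscillations at the
subject's cadence on V and AP acceleration and on the pitch/yaw gyro
(first footfall exactly at the leg start); turns as half-sine yaw
velocity pulses whose duration follows from the subject's peak turning
velocity and the 180 deg angle, overlaid with slower stepping;
Turn-to-Sit as a second, opposite-signed yaw pulse overlapping a
sit-down pulse; quiet sitting again. Gravity (9.81 m/s²) rides on the
vertical accelerometer. Half-sine turn pulses (rather than
minimum-jerk velocity bells) are deliberate: their 10%-of-peak
crossings sit within ~0.05 s of the construction boundaries, so the
turn-extent rule can actually be scored against ground truth at the
0.1 s level.

**Noise and variability.** White Gaussian noise, default SD 0.15 m/s²
and 3 deg/s, chosen so segmentation is solvable but imperfect; no noise
model is published for the emulated device. Within-subject
repetition-to-repetition variability multiplies each kinematic
parameter by 1 + N(0, 0.03); the study reports no within-subject spread,
so 3% is an assumption, exposed as `rep_jitter`.

**What the generator does not emulate** — and therefore what passing
tests do not show about real data: soft-tissue and clothing artifacts,
device-specific noise spectra, gait asymmetries and freezing or
hesitation, non-180-degree or stepped turns, sensor misalignment drift,
and any nonlinearity in the latent-ability links. The generator
validates the *machinery* (segmentation accuracy, feature definitions,
absence of leakage, component recovery, calibration); it cannot
validate clinical claims.

## Numerical choices and degenerate inputs

* Zero-phase filtering uses reflection padding so pulses near record
  edges are not distorted by start-up transients.
* `resample_recording` requires at least two samples; recordings must
  have strictly increasing timestamps (a repeated timestamp is an
  integrity error naming the sample).
* Out-of-range channels (beyond ±4 g, ±500 deg/s) are clipped with a
  warning and a count, not an error.
* Zero-variance predictors are a preprocessing error at fit time (they
  cannot be z-scored) but are silently excluded by the screening step,
  which records them.
* The RMSEP curve covers only component counts reached by at least two
  iterations; NIPALS stops early when the residual response is
  numerically zero.
* VIP boundary ties (exactly 0.83, 1, 1.21) go to the upper bin —
  an arbitrary but documented convention.
* Iterations whose screen keeps fewer than two features are skipped
  with a summary warning; more than 20% skipped is an error, since the
  aggregate would no longer describe the nominal procedure.

## Problem sizes used by the tests

The test suite exercises the full pipeline at 12–36 subjects and the
statistical harness at the study scale (n = 60, m = 78, 100
iterations). Segmentation recovery is scored on 200 simulated trials at
default noise (median per-boundary error ≤ 0.1 s) and 60 noiseless
trials (total-duration error ≤ 0.2 s); component recovery on ten
independently seeded 60 x 78 tables with three latent components and a
generating R² of 0.85. Generator calibration is checked on
4000-subject cohorts against two-standard-error bands. These sizes give
stable pass/fail behaviour at desk scale; all of them are ordinary
function arguments and scale up freely.

## Known limitations

* The 78-feature catalogue is a reconstruction from the documented
  categories (durations, RMS, ranges, jerk scores, turn kinematics,
  steps, gait metrics, regularity) — the emulated study's full feature
  appendix is not public, so individual definitions may differ in
  detail even where names match.
* "Turn duration" is implemented as the First-Turn duration, and the
  per-feature R² column reported alongside VIP is the univariate squared
  correlation with the response; both are documented interpretations of
  ambiguous conventions.
* Descriptives are screened like any other feature and z-scored jointly
  with signal features; whether the emulated analysis exempted them is
  unknown.
* The paired Z-test treats the 100 iteration-level RMSEP differences as
  independent; they share subjects, so the test is anti-conservative in
  absolute terms and is best read as a standardized effect size, the
  same caveat that applies to the emulated analysis.
* Headline clinical numbers (R² = 0.852 etc.) were computed on 60 real
  participants whose raw data is not deposited; nothing at desk scale
  can or should reproduce them, and the package makes no attempt to.
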