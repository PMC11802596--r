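---
title: "Methods: tablet gameplay kinematics, synthetic cohorts, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tablet gameplay kinematics, synthetic cohorts, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinetap)
```

`kinetap` analyzes free tablet gameplay as a motor assessment. This
vignette documents the models and conventions behind each stage, the
choices that were genuinely open, what the synthetic generator does and
does not emulate, and the package's known limitations.

## Data model

A session couples a touch stream (timestamp, x, y, phase ∈
{down, move, up}, pointer id; variable rate ≈ 60 Hz) with an IMU stream
(triaxial acceleration in m/s², rotation rate in rad/s, attitude
roll/pitch/yaw in rad; regular ≈ 20 Hz). Timestamps are seconds from
session start; coordinates are abstract screen points, origin top-left, y
downward (the touch-device convention). The on-disk bundle is a JSON
manifest plus two RFC-4180 CSVs so streams stay inspectable with ordinary
tools. By default only the first pointer seen is analyzed (the dominant-
hand assumption of the coloring task); a switch admits all pointers.

## Gestures and kinematics

An *atomic gesture* is one down…up run. Because the touch rate is
variable, derivatives are actual-timestamp finite differences with no
resampling: speed `v_i = ‖p_{i+1} − p_i‖ / Δt_i` stamped at interval
midpoints, and signed tangential acceleration as the difference of
successive speeds over midpoint spacing. The *signed* convention matters:
the series minimum is the gesture's peak deceleration, the quantity of
interest for motor control of stopping. An unsigned variant and an
optional 3-point coordinate smoother (default off) exist as configuration.

Open choices, resolved as follows:

* **Tap definition** (never standardized): duration < 0.15 s *and*
  displacement < 10 points, both strict. Taps and degenerate gestures
  (< 3 samples, derivatives undefined) are counted but excluded from
  kinematic aggregates.
* **Directness** is displacement ÷ path length over the terminal 25% of
  samples (at least 2); a stationary tail is defined as perfectly direct
  (1). "Final data points" is inherently vague — the tail fraction is a
  parameter.
* **Deviation from a straight line** is the maximum perpendicular
  distance from the chord; the area-between-curve-and-chord alternative
  was noted and not taken (the max is cheaper and scale-interpretable in
  points).

## The 269-feature session representation

No published enumeration of the full feature inventory exists, so the
registry is constructed — and frozen by test — as statistic grids that
total exactly 105 touch + 164 IMU = 269 names:

* touch: 12 per-gesture quantities × 7 statistics (mean, population
  variance, min, max, median, Q1, Q3) = 84; start/end coordinate mean/SD
  (8); inter-gesture-interval statistics (5); tap/count features (8);
* IMU: {acceleration, rotation, attitude, jerk} × {x, y, z, magnitude} ×
  10 statistics = 160; per-axis acceleration-direction sign-change rates
  (3); sample count (1).

Conventions: population variance (÷N) for every dispersion feature, so a
session of identical gestures scores exactly 0; quartiles by linear
interpolation of order statistics; an empty session yields 0 for count
features and an explicit `NA` sentinel (never silent zero) for
aggregates. `minimum_gesture_acceleration` is the session *mean* of
per-swipe acceleration floors, following the convention of reducing each
per-gesture feature to its session mean. The *rate of change of
acceleration direction* is the sign-change count of an acceleration
component per second — the discretization-robust reading; a projected-
angle variant is selectable.

## Movement profiles

Movements differ in duration and sample count, so each gesture's
kinematic timestamps are mapped to [0, 1] and assigned to `n_bins`
(default 10) left-closed bins, the last closed; per bin and per series
(speed, tangential acceleration) five statistics are computed (mean,
median, SD, Q1, Q3). A 10-sample uniformly-timed gesture has 9 midpoint
speeds, so its occupancy under 5 bins is [2, 2, 1, 2, 2] — occupancy
always sums to the *series* length, not the raw sample count. Empty bins
are imputed with the movement-level statistic and flagged rather than
dropped, keeping the design matrix rectangular. Each movement is an
independent sample carrying its session's label; session predictions
average the per-movement probability vectors.

## Classifiers

The session representation feeds a two-layer ReLU perceptron (20–40
units/layer), softmax output, class-weighted cross-entropy, Adam with
β₁ = 0.95, β₂ = 0.99 and inverse-scaling learning-rate decay
(lr/√t, initial 0.001–0.01), written in plain matrix algebra so every fit
is a pure function of its seed. Training is full batch — cohorts are tens
of subjects — with an epoch cap of 500 and a plateau stop (no
improvement over 25 epochs); the stopping rule is a numerical choice, not
a tuned regularizer. The profile representation feeds a gradient-boosted
tree ensemble (xgboost: 500–1000 trees, depth 2, η = 0.1, subsample 0.8,
⌊log₂ p⌋/p column sampling, single thread for determinism).

Class imbalance is offset by balanced inverse-frequency weights
w_c = N/(K·N_c), which satisfy Σ w_c N_c = N and reduce exactly to
duplicating the minority class under full-batch training (checked by
test). Grid search is exhaustive; ties resolve to the smaller model, then
the lower learning rate.

## Validation design

Folds partition *subjects*, never movements: a session's movements and
its feature row stay on one side of every split, enforced by a hard
error. Normalization (feature-wise center/scale) is fitted on the
training fold only; zero-SD training features map to 0 with a warning.
Leave-one-out, stratified repeated k-fold (folds default 4 — the fold
count is a hyperparameter — repeats default 10, shuffled per repeat), and
a nested variant whose inner loop grid-searches without seeing the outer
held-out subjects are provided. Metrics: accuracy = trace/total;
two-class sensitivity/specificity for a designated positive class — in
each clinical pair the affected-vs-TD or DCD-vs-ASD convention designates
ASD (TD/ASD), DCD (TD/DCD) and DCD (ASD/DCD) positive. Above-chance
accuracy (acc − 1/K)/(1/K) is reported both exactly and with both inputs
rounded to two digits first; the two differ visibly for a 3-class
accuracy near 0.57 (72.2% vs 72.7%), and only the rounded convention
lands on the conventionally quoted "73% above chance" for that case.

Feature screening gates each feature per group through a
Kolmogorov–Smirnov normality test against a normal with *estimated*
moments (Lilliefors correction, `nortest::lillie.test`; plain KS for
n < 5), α = 0.05: all-normal routes to ANOVA/Welch t, otherwise
Kruskal–Wallis/Mann–Whitney. Raw p-values are reported by default —
matching the usual practice of publishing unadjusted screens —
with Benjamini–Hochberg behind a flag. Correlations with covariates use
Kendall's tau-b (tie-corrected), chosen for robustness to extreme values.

## The synthetic generator

The generator exists so the full pipeline, including parameter-recovery
experiments, runs with no clinical data. What it emulates:

* **Swipes** follow a minimum-jerk arc-length profile
  s(τ) = L(10τ³ − 15τ⁴ + 6τ⁵). Its tangential acceleration extreme is
  −(10/√3)·L/T², so the generator draws a target deceleration floor and
  stroke length and solves T — the feature extractor then recovers the
  floor to within discretization error (< 2% at ≈ 60 Hz, verified on 100
  gestures).
* **Area dispersion** comes from a sinusoidal perpendicular bow whose
  amplitude is lognormal (`area_log_sd`) scaled by the sensor-noise
  scale, so the noiseless limit degenerates to a perfectly straight
  stroke (directness 1, deviation 0).
* **Stroke endings**: a perpendicular random walk over the final quarter
  (`directness_tail_sd`) drives directness variance.
* **Sampling**: inter-sample jitter uniform ±20% around 1/60 s;
  inter-gesture pauses exponential with mean solved from the target
  gesture rate; taps are 30–100 ms contacts with ≈ 0 displacement.
* **IMU**: attitude channels are damped AR(1) orientation noise at the
  archetype's stationary SDs; rotation channels white; the y-acceleration
  AR(1) coefficient is cos(π·rate/20) so its expected sign-change rate
  equals the `accel_dir_change_rate_y` knob; gesture onsets inject small
  exponentially decaying perturbations (the device's reaction to finger
  impact).

Determinism: a cohort is a pure function of its spec. Per-subject seeds
are taken from a pool drawn sequentially from the master seed's own
stream — a linear counter formula is *not* used because Mersenne–Twister
streams seeded from linearly related integers keep their first draws
weakly correlated, enough to imprint a cohort's group-block layout onto
supposedly exchangeable subjects (this surfaced as a biased null
experiment during development and is why the pool design exists).

The default archetype (gesture rate 0.5/s, tap fraction 0.25, strokes
180 ± 60 points, deceleration floor −2400 ± 300 points/s², attitude SDs
0.02 rad, rotation SD 0.05 rad/s, 6 y-sign-changes/s) describes a
plausible five-minute coloring session of a school-age child; no
published group-level distributional parameters exist, so the
`paper_like_large` preset is calibrated to reproduce the *pattern* of
group differences — ASD: larger area dispersion, orientation variances,
y-direction-change rate, deeper deceleration floor; DCD: noisier stroke
endings, tighter floor spread, slower and shorter stroke production — at
clearly detectable effect sizes for n = 20/group, not the clinical
effect sizes, which are unknown.

What it does **not** emulate: picture content and color/tool choices,
two-handed or multi-touch play, posture changes and tablet pickups,
pressure/size channels, drift or gravity leakage in the IMU, or
heavy-tailed attentional pauses. Passing recovery tests therefore shows
the *pipeline* is correct and sensitive at realistic scales — not that
real TD/ASD/DCD gameplay is separable at these accuracies.

## Problem sizes and numerical choices

The packaged experiments use n = 20 subjects per group and 300 s
sessions (the nominal assessment length) for recovery and null
calibration; recovery classification uses leave-one-out on each pair;
null calibration pools ten 4-fold stratified runs (600 predictions) and
compares against the 95% binomial band around 1/3 — per-prediction
correlation within a cohort makes per-seed bands over-reject. The type-I
experiment screens 500 exchangeable lognormal features at α = 0.05.
Degenerate inputs are handled explicitly: empty streams produce sentinel
features with warnings; constant features are skipped and flagged in the
screen; zero-area and collinear hulls return 0; duplicate timestamps
inside a gesture are an error naming the gesture.

## Limitations

* The feature inventory is *a* faithful reconstruction constrained to
  the published counts and named features, not a recovered original.
* LOOCV and small k-fold accuracies on tens of subjects have wide
  sampling bands; the repeated/nested machinery reduces but cannot
  remove this.
* The MLP has no weight decay or dropout; on noise it can fit folds
  idiosyncratically, which inflates the variance (not the mean) of
  null-cohort accuracy.
* Profile bins of very short gestures are imputed from movement-level
  statistics; with `n_bins` ≫ typical sample counts most bins are
  imputed and the representation degenerates.
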