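---
title: "Gyroscope sway metrics and COP-path prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gyroscope sway metrics and COP-path prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swaycop)
```

`swaycop` analyzes quiet-stance postural sway measured simultaneously by a
trunk-worn triaxial gyroscope and a force platform. This vignette documents
the models behind each stage, the parameters that matter, the numerical
conventions, and what the synthetic cohort does and does not establish
about real data.

## 1. Sway metrics

A gyroscope at the L5 vertebra, near the body's center of mass, reads the
angular velocity of the trunk in three orthogonal axes at 10 Hz. The
per-sample magnitude `MG(n) = sqrt(gx^2 + gy^2 + gz^2)` is the Euclidean
norm of that vector, so it is invariant to any rigid rotation of the sensor
— the property that makes magnitude metrics insensitive to exactly how the
sensor is strapped on. `compute_metrics()` evaluates four amplitude
functionals of `MG` over a mid-trial window:

* **RMS** `sqrt(sum(MG^2)/N)` (rad/s) — overall sway energy;
* **Range** `max - min` (rad/s) — extreme excursion;
* **AC** `(1/fs) * sum(MG)` (rad) — rectangle-rule area under the
  magnitude curve, i.e. total angular distance swept;
* **SD** `sum(|MG(n) - MG(n-1)|)` (rad/s) — total variation of the
  magnitude series.

**Windowing convention.** Metrics are computed on the 11–20 s portion of a
30 s trial, skipping early adaptation and late fatigue. The window is the
half-open interval `(11, 20]`: with samples at `t = n/10` this is the only
endpoint rule that yields exactly `N = 90` samples, which fixes the
convention. Traces that do not span the window raise an error rather than
being silently truncated; non-uniform timestamps are likewise rejected —
resampling is the simulator/IO layer's job, not the metric layer's.

**AC at other rates.** The 1/10 multiplier in the area metric is the
sample interval at 10 Hz; `compute_ac()` generalizes it to `1/fs` so the
result keeps units of rad at any rate.

The force-plate reference is the **COP path length**, the summed Euclidean
increment `sum(sqrt(dx^2 + dy^2))` in mm over the trajectory. Whether the
reference path should be measured over the full 30 s or only over the same
11–20 s window is a genuine design choice; `feature_table(windowing =)`
supports both, and the default is `"window"` so that predictor and target
describe the same interval of the same behavior. Full-trace paths are
roughly the 30/9-fold extrapolation of windowed ones and correlate slightly
less tightly with the windowed metrics.

## 2. The synthetic cohort

No public paired gyroscope/force-plate dataset exists at this design, so
`simulate_cohort()` generates one with the statistical structure a validity
study assumes:

* **COP dynamics.** Each axis follows a discretized Ornstein–Uhlenbeck
  process `x[n+1] = x[n] - theta*x[n]*dt + sigma*sqrt(dt)*eps`. The OU
  process is the simplest model with the two features that matter for path
  statistics: persistent random motion and mean reversion (bounded sway).
  It is *not* a mechanical pendulum ODE — the analysis consumes only path
  functionals, not dynamics, so two parameters suffice. The
  anteroposterior axis gets 1.5× the mediolateral intensity; quiet-stance
  sway is anteroposterior-dominant, and with the exact ratio unknowable we
  fix a representative one.
* **Gyroscope link.** Quiet stance is well approximated by an inverted
  pendulum pivoted at the ankle: trunk lean angle ≈ COP excursion divided
  by the effective COM height (`pendulum_length_mm`, default 1000 mm). The
  gyroscope reads the finite-difference derivative of that angle (A-P →
  pitch, M-L → roll); yaw carries no sway signal. Independent Gaussian
  noise of sd `gyro_noise_sd` is added per axis.
* **Common internal rate.** Both streams are simulated at 50 Hz and
  decimated to the output rates, so the derivative is formed before
  down-sampling and is not aliased. A consequence worth knowing: the
  decimated gyro samples *instantaneous* angular rates, so the identity
  "AC = windowed COP path / pendulum length" — exact when the gyro is
  derived at the COP's own rate — becomes approximate at the cohort level
  (rank correlations stay above 0.95 noise-free).
* **Cohort structure.** 53 subjects × 6 conditions (double, tandem and
  single-leg stance, eyes open/closed), 30 s trials. Per-condition
  intensities `(1.3, 1.8, 2.5, 3.5, 5.0, 7.0)` mm·s^-1/2 increase strictly
  over that order. With `ou_theta = 0.5` /s the stationary per-axis sd is
  `intensity/sqrt(2*theta)`, i.e. ~1.3 mm in the easiest condition up to
  ~7 mm (M-L) in the hardest — typical quiet-stance amplitudes. Each
  subject carries a log-normal susceptibility multiplier
  (`subject_sd = 0.35` on the log scale) shared across their six trials,
  which produces the right-skewed full-trial COP path distribution with
  the bulk below 1000 mm that healthy cohorts show. `gyro_noise_sd =
  0.002` rad/s is a consumer-grade gyro noise floor, small relative to the
  weakest condition's signal (~0.008 rad/s).
* **Reproducibility.** One seed per cohort; each trial's RNG substream is
  derived deterministically from (subject, condition), so cohorts are
  bit-identical under regeneration and insensitive to generation order,
  and the caller's RNG state is never touched.

Trials are always the full 30 s. Real protocols sometimes shorten a trial
a participant cannot hold; a 15 s trial cannot contain the 11–20 s window
at all, so the shortened-trial case is deliberately out of scope and such
traces raise an insufficient-duration error.

**What passing tests on this cohort do and do not show.** The simulator
encodes, by construction, a monotone coupling between trunk angular
velocity and COP path — the very thing a human validity study has to
establish empirically. Tests on synthetic cohorts therefore verify that
the *pipeline* recovers structure that is present (and reports none when
targets are permuted); they cannot certify any particular sensor. Real
data also contain what the simulator omits: non-stationary drifts,
hip-strategy sway that breaks the single-pendulum link, sensor bias
instability, and heavier-tailed subject effects, so correlations on real
cohorts (ρ ≈ 0.86–0.89 is typical of good trunk sensors) sit below the
ρ ≈ 0.98 the clean simulation reaches.

## 3. Prediction models

`run_model_comparison()` trains five regression models of COP path on the
four metrics under a shared seeded k-fold partition (k = 5), a paired
design in which per-fold results are directly comparable across models.
Features are z-scored with training-fold statistics only; data-derived
hyperparameters use training-fold targets only. Defaults, with the
reasoning where a choice was open:

* **lsboost** — gradient boosting with squared-error loss, 100 trees.
  Depth 3 and learning rate 0.1 are the conventional small-data defaults;
  both are exposed in `model_spec()`.
* **bagging** — 100 bootstrap-aggregated trees grown on all four features
  (`mtry = p`, which reduces a random forest to pure bagging).
* **svm** — RBF-kernel epsilon regression. The epsilon tube is set per
  training fold to one tenth of a robust sd estimate of the targets,
  `(IQR(y)/1.349)/10` (1.349 is the IQR of a standard normal). The target
  is standardized internally so the default cost C = 1 is on a sensible
  scale; C is exposed in the spec.
* **ann** — feedforward net, two hidden layers of 3 and 4 tanh nodes,
  linear output, trained full-batch by BFGS (max 1000 iterations) on the
  standardized target, weights initialized from a seeded N(0, 0.5). With
  36 parameters and ~250 training rows, full-batch quasi-Newton is more
  stable than stochastic training and is deterministic given the seed.
* **gp** — Gaussian process regression with squared-exponential kernel and
  a constant mean basis whose coefficient is profiled out by generalized
  least squares. The signal amplitude starts at `sd(y)/2`, the
  length-scale at the median pairwise feature distance, the noise sd at
  `sd(y)/2`; all three are then optimized by BFGS on the log marginal
  likelihood. A 1e-8 jitter keeps the Cholesky factorization stable.

Fold assignment is at the trial level by default, matching the usual
design of such studies; because six trials share a subject this lets a
subject appear in both training and test folds, a mild leakage risk.
`make_folds(groups = subject_id)` assigns whole subjects to folds for the
conservative alternative.

## 4. Agreement statistics

All statistics are implemented from first principles and cross-checked
against naive-loop oracles in the test suite.

* **Spearman's ρ** — Pearson correlation of mid-ranks (ties get average
  ranks), two-sided p from `t = rho*sqrt((n-2)/(1-rho^2))` on n−2 df.
  Rank correlation is used because sway metrics are non-normal. Constant
  inputs raise an error rather than returning NaN.
* **ICC(2,1)** — the label "ICC(2,1), two-way mixed" conflates textbook
  conventions, so the package states its choice explicitly: single-measure
  **absolute agreement** from the two-way ANOVA decomposition,
  `(MSR − MSE)/(MSR + MSE + (2/n)(MSC − MSE))` for two raters, with the
  McGraw–Wong F-based 95% CI. Absolute agreement is the right form for
  method comparison because it penalizes systematic offsets that
  consistency ICCs and Pearson r ignore. Identical inputs return ICC 1
  with a degenerate CI of [1, 1].
* **Bland–Altman** — bias = mean difference, limits of agreement
  bias ± 1.96·sd of differences (sample sd, n−1 throughout). CV% is
  defined as `100 * sd(differences) / mean(pairwise averages)`; when the
  grand mean is zero the CV is undefined and returned as NA with a
  warning while bias and LoA are still reported.
* **Slope/offset** — OLS of *predicted on actual* (`predicted = m*actual
  + c`), the orientation used when judging calibration of a prediction
  against a gold standard; the preferred model has m closest to 1 with
  the smallest c.

Validity correlations (`validity_table()`) are pooled over all trials of
all conditions; per-condition correlations would each see a narrower
intensity range and are not computed. p-values are reported raw, with no
multiple-testing correction across the four metrics.

## 5. Problem sizes and determinism

The shipped tests exercise the full default cohort (318 trials) for the
structure-recovery and negative-control checks, 1000-replicate random
series for the metric and statistics oracles (tolerances 1e-12 and 1e-10),
200 Monte-Carlo replicates for the OU monotonicity property, and 6-12
subject cohorts elsewhere. Every stochastic component — cohort, fold
partition, bootstrap resampling, network initialization — draws from a
seed that propagates from one `study_config()` field, and `run_study()` is
byte-identical across repeat runs with the same config.

## 6. Known limitations

* The simulator's pendulum link is single-segment and small-angle; hip
  strategy, which matters in older adults, is not modeled.
* Only amplitude metrics are implemented; frequency-domain sway
  parameters, directional (A-P/M-L) metrics and sway-ellipse areas are
  out of scope, as is any accelerometer channel.
* Hyperparameters are fixed defaults, not searched; results on other data
  should be read as achievable-with-defaults, not best-possible.
* The agreement module implements exactly the two-rater single-measure
  case; repeated-measures and >2-rater ICC forms are not provided.
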