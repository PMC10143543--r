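---
title: "Dual-system gait analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-system gait analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualgait)
```

`dualgait` implements two independent pipelines that extract spatiotemporal
gait features from simultaneously worn sensing systems — plantar-pressure
instrumented insoles (100 Hz) and ankle-mounted IMUs (59.5 Hz) — together
with the statistics used to compare them and a machine-learning stage that
detects Parkinsonian gait impairment from the extracted features. Because
clinical recordings of this kind are rarely shareable, the package also
contains a synthetic signal generator that renders both modalities from one
ground-truth gait event timeline; every downstream stage is validated against
that shared truth. This vignette explains the models, the tunable parameters
and the decisions taken where the design was genuinely open.

## The gait cycle model

A gait cycle runs from one right heel strike to the next. Eight contact
events partition it, in fixed order: right heel strike (`t01`), left toe off
(`t02`), right toe strike (`t03`), right heel off (`t04`), left heel strike
(`t05`), right toe off (`t06`), left toe strike (`t07`), left heel off
(`t08`), followed by the successor events `t01'` and `t02'`. From these time
points the insole pipeline computes fourteen durations `a01..a14` (single
support, double support, side stance, loading response, terminal stance,
pre-swing, cycle durations, cadence) and eleven cycle-normalised fractions
`a15..a25`. Two identities hold by construction and are asserted in the test
suite: `a03 = a06 + a10` (double support is the sum of the two loading
responses) and `a02 + a04 = a09`.

One published formula is internally inconsistent: right single support is
printed identically to left side stance (`t02' − t05`). The package defaults
to the biomechanically consistent mirror of left single support,
`a01 = t05 − t02` — the interval when only the right foot is on the ground —
and offers `paper_literal = TRUE` in `compute_insole_features()` to evaluate
the printed formula instead. Cadence `a14 = 1/(t02' − t01)` is kept exactly
as defined (a cycle-based rate in 1/s), never silently converted to
steps/min.

## The synthetic generator

`simulation_spec()` fixes the study conditions; `sample_gait_timeline()`
draws a session. The defaults were chosen once, from normative gait
literature where no source value exists, and define the conditions under
which all package-level claims are tested:

* **Phase fractions** 0.12 / 0.20 / 0.40 / 0.50 / 0.62 / 0.65 / 0.90 for
  `t02..t08`: normative gait-phase proportions (62% stance, ~12% loading
  response / double support per side). The `t03` fraction (0.20) is the one
  value with no external anchor; it places contralateral foot-flat shortly
  after the opposite toe off, inside the window the event ordering allows.
* **Cycle durations** 1.3 / 1.1 / 0.9 s for slow / normal / fast walking,
  with coefficient of variation 0.03. Session stride counts vary (SD 2
  around a mean of 25, scaled by 1.15 / 1.0 / 0.85 across speeds) the way a
  fixed 10 m out-and-back walk varies: slower walks take more, shorter
  strides.
* **Timing jitter** is *sequential*: each sub-phase interval
  `t(j−1) → t(j)` receives an independent Gaussian perturbation and event
  times accumulate them. This random-walk structure was a deliberate choice
  over independent per-event jitter: it is how sub-phase variability
  propagates physiologically, and it keeps the variance of a composite
  interval equal to the sum of its parts, so the impairment signature stays
  where it is injected.
* **Impairment model**: a clinician rating r (0–4) scales the SD of the two
  loading-response intervals by `1 + 0.5·s·r`, the right pre-swing interval
  by `1 + 0.25·s·r`, and shifts the left heel-strike fraction by `0.002·s·r`
  (step-time asymmetry), where `s = effect_scale`. The hierarchy — loading
  response primary, pre-swing secondary, asymmetry tertiary — encodes the
  clinical finding the classifier stage is meant to recover: gait-quality
  degradation manifesting first in loading-response variability, with
  pre-swing and double-support variability rising as downstream
  consequences. `effect_scale = 0` removes the effect; `effect_scale = 3` is
  the strong-effect condition (~3× loading-response SD at rating 1) used by
  the sensitivity checks.
* **Rendering**: regional forces are trapezoids whose rising edge crosses 5%
  of plateau amplitude exactly at the contact event and whose falling edge
  crosses 4% exactly at the release event, mirroring the detector's default
  relative thresholds, with 50 ms ramps. The ankle gyroscope Z-axis gets one
  positive Hann lobe per swing (250 dps peak, centred mid-swing) flanked by
  negative Gaussian dips at toe-off (−80 dps) and initial contact (−40 dps),
  the canonical sagittal shank-rotation morphology. Sensor noise defaults:
  0.05 N/cm² per pressure cell, 2 dps gyroscope, 0.02 g accelerometer.

What the generator does *not* emulate: turns, freezing of gait, non-walking
activity, sensor drift and saturation, footwear-dependent pressure
redistribution, or biomechanically coupled kinematics (the two modalities
share event timing but not a common forward-dynamics model). Tests passing
on this generator therefore demonstrate the correctness and internal
consistency of the pipelines, not their accuracy on arbitrary clinical
recordings.

## Insole event detection

`preprocess_insole()` low-pass filters each pressure channel (zero-phase
4th-order Butterworth) and subtracts the per-channel median as the quiescent
baseline — every cell is out of contact most of each cycle, so the median
estimates the resting level robustly; subtracting a low percentile instead
would lift the post-filter ripple into the detector's hysteresis band. The
default cutoff is 20 Hz: comfortably above the gait band, but gentle enough
that the ~50 ms contact edges, which carry all the timing information, are
not distorted. (At 10 Hz the edge ringing of a 4th-order zero-phase filter
biases 5%-threshold crossings by roughly 18 ms — nearly two samples — which
is why the sharper setting was rejected.)

`detect_gait_events()` runs a four-state contact machine per foot — swing,
heel-only, foot-flat, toe-only — on thresholded heel and toe regional forces
(rear five cells = heel, front six = toe, configurable). Thresholds default
to 5% of the session's 95th-percentile regional force with a 20% hysteresis
release band (Schmitt trigger), so they scale with signal amplitude and
ignore threshold-straddling chatter. Each state entry from its canonical
predecessor emits one event; the merged left/right stream is assembled into
complete cycles by exact pattern match, discarding partial edge cycles and
counting out-of-order ones in diagnostics.

## IMU event detection

Mid-swing peaks are detected on the gyroscope Z axis with the relative
height rule `max(50, 0.3 · max(sz))` dps, a 0.5 s minimum peak distance and
a 0.1 s minimum width at half height. Toe-off and initial contact are
negative-going dips, found on the inverted signal at fixed depth thresholds
of 15 dps and 5 dps respectively; since the thresholds are printed for the
inverted signal, both are implemented as dip depths, with the toe-off dip
required deeper than the initial-contact dip. No assignment rule is
published, so each mid-swing peak takes the nearest qualifying dip before it
as toe-off and the nearest after it as initial contact, within a 0.5 s
window; strides missing either are dropped and counted. Features computed
per foot keep `stance + swing = cycle` exactly by construction. Double
support is deliberately never computed from IMU data — it needs both
sensors, and the feature policy is single-sensor. Two published feature
names have no printed definition ("normalized stride length", "normalized
walking speed"); the package implements declared surrogates (swing angular
excursion × a configurable leg-length factor, and that surrogate × cadence)
and labels them as such.

Walking bouts are taken from a manual interval table when supplied (the
study's own practice); the automatic mode thresholds the 1 s moving RMS of
gyroscope magnitude at 20 dps, merges gaps under 1 s and drops bouts under
3 s.

## Agreement statistics

For each common feature (walking cadence, left/right cycle duration,
left/right single support, left/right stance, number of steps) the
comparison stage: removes sessions where either system counted fewer than 3
steps; min–max-scales the IMU values onto the insole range (insoles as
reference axis; affine, so Pearson r is untouched); flags outliers whose
paired difference exceeds 3 robust z-units (median/MAD, no flags when
MAD = 0); computes Pearson r and ICC(3,1) on the unflagged pairs; and
reports Bland–Altman mean difference and limits `mean ± 1.96·SD`.

ICC(3,1) — two-way mixed-effects, consistency, single rater — is the
standard reading of "single, fixed raters" with the two systems as raters:
`(MSR − MSE) / (MSR + MSE)` for k = 2. Because the role of the three speed
classes in the published analysis is ambiguous (pooled with speed as a
factor, or stratified), both are emitted: the pooled value is the headline,
per-speed values ride along in `per_speed_icc`. The implementation computes
the mean squares directly from the closed-form sums; the test suite checks
it against an independent `aov()` decomposition to 1e-10 and exploits the
identity ICC = r on variance-matched columns.

## Impairment classification

Only normal-speed sessions enter the classifier, labelled impaired when the
clinician gait-item rating exceeds 0. Three feature sets are evaluated —
insole-only, IMU-only, combined — with four models: radial-kernel SVM
(cost 1, probability outputs), random forest (100 trees), gradient boosting
(xgboost, 100 rounds, depth 3, learning rate 0.1, exact split finding — the
histogram method mis-places split points in the empty margins typical of
n ≈ 76 problems), and AdaBoost. No R AdaBoost package is available in the
supported dependency set, so a standard SAMME boost over depth-1 `rpart`
stumps (50 iterations, margin-based scores) is implemented in-package.

The published validation protocol is unstated, so the package uses
subject-grouped stratified 5-fold cross-validation: a subject's ON and OFF
sessions never straddle the train/test boundary, which is the leakage that
would otherwise inflate every metric. Standardisation is fitted on training
folds only. Threshold metrics (accuracy, F1, precision, recall; impaired =
positive class) are computed on pooled held-out predictions; AUC is averaged
over fold-level AUCs, because pooling mixes per-fold probability scales and
can depress the AUC of a perfectly ranked classifier.

Feature importance defaults to permutation importance on held-out folds,
scoring the increase in log-loss when one feature is permuted (3
permutations per feature and fold, averaged over 3 repetitions of the whole
cross-validation). Log-loss is scored rather than AUC because AUC saturates
exactly when the problem is well separated, returning zero drops for every
feature; and rankings among correlated features are unstable under a single
fold assignment, hence the repetition averaging. An optional TreeSHAP engine
(`engine = "shap_gb"`) is exposed for the gradient-boosting model.

## Numerical choices and degenerate inputs

* Event times are reported at the first sample satisfying a condition, so
  noise-free recovery is one-sided within one sample (10 ms insole, ~16.8 ms
  IMU); the test suite asserts exactly that bound.
* Timeline sampling retries a cycle up to 100 times if jitter breaks event
  ordering, then fails with a diagnostic.
* All-zero pressure recordings pass through preprocessing with a warning;
  all-flat gyroscope signals, sub-threshold forces and bouts shorter than
  the minimum peak distance return empty event sets rather than errors; zero
  detected cycles raises a "no steps detected" error so the caller can
  distinguish absence of gait from pipeline failure.
* Min–max scaling refuses constant inputs by name; MAD = 0 disables outlier
  flagging; constant features get importance 0.
* Every stochastic step streams from one master seed (`with_seed()` restores
  the caller's RNG state; per-session child seeds make cohorts reproducible
  under subsetting).

## Problem sizes

The shipped tests and the acceptance script run, by choice, at the scale of
the emulated study: 12-cycle sessions for event-recovery checks, a
19-subject × 3-speed × 2-repetition cohort (~114 sessions) for the agreement
analysis, and 76 normal-speed sessions (19 subjects × 2 medication states ×
2 repetitions) for the classification stage, with 20 label permutations for
the chance-level control.

## Known limitations

* The renderers and detectors share the 5%/4% relative-threshold convention;
  detectors with very different absolute thresholds will show a constant
  edge-timing bias on synthetic data.
* IMU cadence is a cycle rate (1/cycle duration) while the insole cadence
  `a14` uses the printed `1/(t02' − t01)` definition; the two differ by the
  left-loading-response offset and are reconciled by the range scaling in
  the agreement stage, not by redefining either feature.
* The classification stage inherits the cohort's class imbalance (~12 of 76
  sessions unimpaired); fold-level AUCs on single-class folds are undefined
  and excluded from the average.
* Synthetic results validate implementation correctness, not clinical
  performance; none of the published real-data coefficients are claimed or
  reproduced here.
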