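---
title: "Detecting emergency braking intention from EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting emergency braking intention from EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

brakeintent implements a complete decoding pipeline for a two-class
brain–computer interface: discriminating the seconds of *braking intention*
that precede an emergency stop from ordinary driving, using 8 channels of
scalp EEG (10–20 positions F3, F4, C3, C4, P3, P4, O1, O2) sampled at 128 Hz
together with a 6-channel inertial measurement unit (IMU) on the same clock.
This vignette explains the models behind each stage, the tunable parameters
and their defaults, what the synthetic-data generator does and does not
emulate, and the numerical choices that an archival implementation has to
make explicit.

## The pipeline at a glance

```{r}
library(brakeintent)

session <- simulate_session(sim_config(duration_s = 1500, seed = 1))
dataset <- build_dataset(session, step_ms = 125, feature = "ar", ar_order = 10)
cv <- kfold_cv(dataset, k = 5)
glance(cv)
```

Training mode: sliding 1-s windows are cut from the session at a
configurable step (62.5, 125 or 250 ms); executed braking events are found
from the IMU; windows ending inside the pre-braking period of an event are
labeled "braking intention", quiet windows far from events "normal driving";
each window is band-pass filtered, cleaned by ICA, reduced to a feature
vector, and a three-layer perceptron is trained and cross-validated.
Testing mode replays a session through a rolling 1-s buffer and applies the
same chain per step, so online and offline predictions are bit-identical by
construction (a property the test suite asserts).

## Automatic labeling from the IMU

An executed braking event shows up as a high-variance transient in both the
accelerometer and the gyroscope. A 1-s IMU window is *event-positive* when
the standard deviation of its 3-axis vector magnitude exceeds 120 counts
(gyroscope) or 12 counts (accelerometer); either sensor suffices. Runs of
positive windows within 5 s collapse to a single event stamped at the first
step-grid time the crossing is visible.

Windows ending in the half-open interval `(e − P, e]` of an event `e` are
braking-intention samples, where the pre-braking period `P` is one of
200–1000 ms. With `P` an exact multiple of the step this yields exactly
`P/step` samples per event — 8 for 1000 ms at 125-ms steps, hence 62 events
give 496 braking samples — and `ceiling(P/step)` otherwise (the window grid
holds every end with `k·step < P`). Everything inside 5 s *after* an event
is discarded as unstable; normal-driving windows must additionally be quiet
in the IMU and at least 5 s from every event on both sides, and are
subsampled (seeded) to at most twice the braking count so that class
imbalance stays near the 1.9:1 ratio the classifier is designed around.
Two interpretations the underlying description leaves open are resolved
here: the 5-s discard applies only after events (the pre-event side is
already governed by the pre-braking window plus the 5-s quiet margin for
normals), and the interval `(e − P, e]` is half-open so that no window is
ever counted by two adjacent events.

## Preprocessing: band-pass, infomax ICA, approximate entropy

Each window is filtered to 1–60 Hz — the delta through gamma range, with the
60-Hz band edge also suppressing mains interference — by a 4th-order
Butterworth applied forward–backward. Zero-phase filtering matters because a
causal filter's group delay would smear a 1-s window whose label depends on
its end time; the channel mean is removed first because `filtfilt` edge
transients scale with the DC offset on 128-sample segments.

Artifact handling follows the blind-source-separation route: an extended
infomax ICA is fit per window (natural-gradient ascent, per-component
super/sub-Gaussian switching by the sign of the excess kurtosis, random
orthogonal initialization from a per-window seed, at most 500 iterations,
update tolerance 1e-7). Components are scored by approximate entropy
ApEn(m = 2, r = 0.2·SD) — the Pincus defaults; low ApEn means a regular,
predictable trace, which is what blinks and head-movement artifacts look
like, while broadband EEG scores high. Components with ApEn below the
threshold (default 0.35) are zeroed and the window rebuilt through the
mixing matrix. The default sits near the 1st percentile of ApEn over clean
simulated components (≈0.40) and far above smooth blink-like bursts (<0.1).
Two safety rules: a threshold of 0 disables removal exactly (output equals
input to machine precision), and if every component is flagged the window is
returned unfiltered with a warning — the pipeline never fabricates an
all-zero EEG window. Fitting ICA per 1-s window rather than per session
keeps the online and offline paths identical; the per-window seed is derived
from the window's start sample so the decomposition does not depend on the
order in which windows are visited.

## Features

**Relative band power.** Each 128-sample channel is zero-padded to 512
points, giving a 0.25-Hz periodogram resolution, and summed over delta
(1–4), theta (4–8), alpha (8–14), beta (14–30) and gamma (30–60 Hz); band
edges are half-open `[low, high)` so adjacent bands never double-count a
bin. Relative powers `rPB_i = PB_i / Σ PB_i` sum to one per channel; the
feature is the 40-vector of all five bands on all eight channels. No taper
is applied by default (a Hann taper is available behind a flag); since the
relative powers divide out any global normalization, the choice matters
little. An all-zero channel falls back to the uninformative uniform 0.2 per
band and is flagged.

**Burg autoregressive coefficients.** Each channel is mean-centered and fit
with an AR(p) model, `x_t = Σ φ_i x_{t-i} + ε_t`, by the Burg recursion,
which minimizes the summed forward and backward prediction-error power and
guarantees reflection coefficients |k| ≤ 1, i.e. a stationary fit even on
one second of data. The feature concatenates, per channel in fixed
montage order, the p coefficients and the innovation variance — p + 1 values
per channel, reproducing the classifier input sizes 32 to 168 for
p = 3…20. The coefficients are exactly amplitude-invariant; the variance
term carries the residual power that the normalized coefficients cannot.
The window mean (the model constant) is recorded but excluded. The package's own
Burg implementation is cross-checked in the tests against `stats::ar.burg`
(same recursion, independent code) and against the least-squares estimator
on long series (max |Δφ| < 0.02 at n = 4096).

## Classifier

A three-layer perceptron: D inputs (40 or 8·(p+1)), one sigmoid hidden layer
(default 50 units), and a 2-unit softmax output trained by cross-entropy.
Features are z-scored with constants computed on the training split only and
stored in the model — with raw AR coefficients spanning orders of magnitude
across lags, standardization is what makes the quoted iteration counts
(convergence within ~100–200 full-batch iterations) plausible. Training is
full-batch gradient descent with an adaptive step (grow 5% on improvement,
halve on worsening), which keeps runs deterministic per seed and invariant
to sample order; with a validation set, training stops after 10
non-improving iterations and the best-validation weights are kept. Weight
init is symmetric uniform scaled by fan-in. Class order is fixed and
documented everywhere: index 1 = normal, index 2 = braking; exact 0.5 ties
break to normal. Analytic gradients are verified against central finite
differences to 1e-6 relative error in the test suite.

## Evaluation

Braking intention is the positive class: sensitivity is braking recall,
specificity is normal recall. AUC integrates the ROC by trapezoids with tied
scores grouped, which equals the normalized Mann–Whitney U with ties counted
half — asserted against direct pair counting. Cross-validation is stratified
5-fold (class ratio preserved within one sample per fold; per-class
remainders are spread so fold totals for 1418 samples come out
284/284/284/283/283), with standardization refit inside every training fold.
Because the fold-mean and pooled aggregations of "CV accuracy" can differ,
`glance()` reports both. Parameter sweeps (AR order 3–20, step size
62.5/125/250 ms, pre-braking period 200–1000 ms, hidden width 10–1000) refit
the labeling from the session whenever the swept parameter changes the
windowing or labels, exactly as the training mode would.

## The synthetic-data generator

The generator is the package's test bed, emulating the statistics the
pipeline assumes rather than the biophysics of the scalp:

* Braking events arrive with shifted-exponential gaps (minimum 7 s; mean
  23 s), at least 10 s from the session edges; the minimum gap guarantees
  the 5-s discard zone and the following pre-braking window can never
  collide. Reaction times (stimulus to executed braking) are normal,
  876 ± 150 ms, truncated at 300 ms.
* Background EEG per channel is a stationary AR(10) process whose poles give
  a 1/f-like envelope plus an alpha resonance (band averages decrease
  monotonically from delta to gamma, as asserted in the tests). During the
  600-ms signature window before each braking time the generating poles
  shift — the alpha pole loses radius and drifts within its band while a
  low-beta pole sharpens — scaled by `signature_strength`. The shift is a
  genuine change of temporal dynamics that moves little power across the
  coarse 5-band grid, so the AR feature is discriminative by construction
  and band power only weakly so; `signature_strength = 0` gives a null
  session on which the whole pipeline must cross-validate at chance — the
  leakage guard in the acceptance tests. That guard runs on non-overlapping
  windows with balanced classes: windows cut at sub-second steps share
  87.5% of their samples, so random-fold CV is optimistically biased on
  overlapping windows even with no signal (a property of the mix-then-split
  protocol, worth remembering when reading the absolute CV numbers), and
  independence is needed for a binomial band around 50% to be a valid
  test. Interpolating pole radii and
  angles (rather than coefficients) keeps every intermediate process
  stationary. After an event, baseline dynamics resume through a 2-s blend
  inside the discard zone, so the single regime switch never reaches a
  training or scored window.
* The IMU is per-axis Gaussian baseline noise (quiet-window magnitude SD
  well under the 120/12 thresholds) plus a 300-ms raised-cosine burst on all
  six axes at each braking time, calibrated so the within-1-s-window
  magnitude SD is twice the threshold — detection is unambiguous by
  construction.
* Optional blink-like contaminants (smooth 400-ms frontal bursts at a
  configurable rate) exercise the ApEn artifact rejection; they are a
  caricature of ocular artifacts, not an electro-oculographic model.

What passing tests on this generator show is that the *pipeline* is correct
and leak-free and that its qualitative orderings (AR > band power, accuracy
peaking near the true signature duration and degrading at 1000 ms, matched
AR order ≥ too-short order) follow from the stated mechanism. They do not
certify performance on human EEG: real scalp recordings have non-stationary
rhythms, volume-conducted correlated channels, richer artifacts and
subject-specific signatures, none of which the generator claims to model.

## Online detection

The streaming detector keeps a rolling 128-sample buffer, appends one step
of new samples per cycle, and runs the identical preprocess → featurize →
classify chain; the first prediction fires at t = 1 s. A detection event
requires 2 consecutive braking predictions by default (a debounce; 1
reproduces undebounced per-window firing). Lead time is measured to the
IMU-detected braking onset. On default synthetic sessions the detector
recalls all events with a positive mean lead of roughly half a second (the
acceptance script reports the exact recall, lead time and false-alarm rate
it measures); the false-alarm rate is limited by the per-step
false-positive rate on quiet driving combined with the strong correlation
of 87.5%-overlapping windows, so debouncing deepens detections only
slowly — deployments wanting very low false-alarm rates should raise
`smoothing_n` or the probability threshold and accept shorter lead times. The streaming path is asserted bit-identical to batch
segmentation at every tested step size.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run entirely on synthetic
sessions sized for a desk machine: a 1500-s training session (≈62 events,
≈1500 labeled windows) for the headline cross-validation, 420–480-s sessions
for the null guard and the sweeps, and a 180-s fresh session for streaming.
Numerical conventions collected in one place: windows are half-open
`[start, start + 1 s)` with 0-based sample indexing; the pre-braking
interval is `(e − P, e]`; boundary comparisons use a 1-µs tolerance, far
below any step size; ICA whitening regularizes eigenvalues below 1e-10 of
the largest (with a warning) rather than failing on rank-deficient windows;
`softmax` subtracts the row maximum before exponentiating; cross-entropy
clamps probabilities at 1e-300; a constant series has ApEn 0 by convention;
and an all-flagged ICA window is returned unfiltered with a warning.

## Known limitations

* The generator's signature is stationary within its window and identical
  across channels and events up to noise; real pre-movement EEG is neither.
* ICA on 128 samples of 8 channels is statistically marginal; it is kept
  per-window to preserve online/offline equivalence, and its artifact gate
  (ApEn threshold) is calibrated on simulated, not human, contaminants.
* The false-alarm behaviour of the streaming detector reflects the synthetic
  class overlap; absolute rates do not transfer to real recordings.
* Hardware concerns — electrode impedance, packet transport, the 48-ms
  per-cycle compute budget of an embedded implementation — are out of scope.
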