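---
title: "Individualized EEG-based stress regression: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized EEG-based stress regression: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stresseeg)
```

## The problem

During a stress-relax session — a 6-min arithmetic stressor with social
pressure (the MIST protocol), followed by a 5-min virtual-reality relaxation
and a final eyes-closed rest — a participant's momentary stress is probed
eight times with a single-question survey: "What is your level of stress on a
scale from 1 to 5?" (the self-perceived stress level, SPSL). Meanwhile four
frontal EEG channels (Fp1, Fp2, F5, F6) are recorded at 256 Hz. The goal is
an *individualized* regression model per participant that predicts the SPSL
as a continuous quantity from spectral EEG features, rather than classifying
two or three coarse stress levels.

`stresseeg` implements this pipeline end to end, together with a synthetic
session generator so that every stage is testable without human recordings.

## Preprocessing

Each phase is acquired as a separate recording and processed independently
(filters never run across phase boundaries). The chain is:

1. **Notch filter**, 48–52 Hz stopband, to remove 50 Hz mains coupling.
   Realized as a 2nd-order Butterworth band-stop applied forward–backward;
   the order is a package choice (stable at 256 Hz, >100 dB attenuation at
   50 Hz after the double pass, <1 dB ripple by 45/55 Hz).
2. **Bandpass filter**, 2–48 Hz, 4th-order zero-phase Butterworth. "Zero
   phase" is read as forward–backward application of the 4th-order design,
   giving an effective 8th-order magnitude response and exactly zero phase
   lag (verified by lag-0 cross-correlation of a 10 Hz probe).
3. **Resampling to the nominal phase length.** Recording onsets were marked
   manually, so durations differ from the theoretical span by a few seconds.
   The recording is mapped onto exactly `nominal_s * 256` samples by
   Fourier-domain resampling: the spectrum is truncated/extended to the
   output length. By this point the signal is band-limited to 2–48 Hz, far
   below either Nyquist rate, so the operation is essentially exact (probe
   band powers move by well under 2%). A rational-factor polyphase design
   was considered and rejected: near-unity ratios such as 92,890→92,160
   reduce to impractically large polyphase factors. Recordings deviating
   more than 10% from nominal are rejected as corrupt.
4. **Central-minute extraction** for the final rest: only the centered 60 s
   of the ~2-min recording is analysed.
5. **Epoching** into non-overlapping 2-s windows: 180 epochs for the MIST
   test, 150 for relaxation, 30 for the rest minute — 360 per session
   (`60 s/min × 12 min / 2 s`).
6. **Outlier zeroing**: any epoch whose absolute amplitude exceeds 75 μV on
   *any* channel is zeroed across all channels and flagged. The rule is
   applied to post-filter amplitudes, before standardization, following the
   pipeline ordering; the whole epoch (not single channels) is zeroed
   because artifacts are tagged at epoch level.
7. **Detrending and standardization**, per epoch and channel: the
   least-squares line is removed, then the mean is subtracted and the result
   divided by the standard deviation, so every live channel-epoch has mean 0
   and SD 1 to within 1e-9. An epoch that is constant after detrending
   (e.g. a pure ramp) has no defined standardization; it is zeroed and added
   to the outlier mask rather than producing a division by zero.

## Features

Per epoch, the power spectral density of each channel is estimated by a
single-segment periodogram of the Tukey-windowed 512-sample epoch (taper
fraction 0.25; the window family is part of the protocol, the fraction is a
package default exposed in the configuration). Band powers are integrals of
the PSD by the trapezoidal rule over the bins whose centers fall in
`[low, high)` for Delta (1–4 Hz), Theta (4–8), Alpha (8–13), Beta (13–25)
and Gamma (25–45). Two derived indices complete the seven features:

* **Relative gamma** `RG = P_Gamma / (P_Alpha + P_Theta)`, computed from the
  channel-averaged powers (consistent with the channel-averaged PSD; whether
  per-channel ratios should be averaged instead is not determined by the
  protocol, and the channel-averaged reading was chosen). A zeroed epoch
  would divide 0 by 0; RG is defined as 0 there so the matrix stays dense,
  and the epoch remains flagged.
* **Alpha asymmetry** `AA = P_Alpha(F6) − P_Alpha(F5)`, the right-minus-left
  frontal alpha difference.

Powers are used on their absolute scale (not log-transformed). Note that the
Delta band nominally starts at 1 Hz while the bandpass starts at 2 Hz; the
band edges are kept verbatim, so Delta's 1–2 Hz content is attenuated by the
preceding filter. This interaction is inherited from the protocol as stated
and left undocumented there; we follow the stated band table.

Features are smoothed by a 30-s (15-epoch) moving average, centered and
truncated (shrinking) at recording boundaries — edge handling is not
specified by the protocol; the centered-truncated window avoids phase lag.
Smoothing runs per phase recording, then rows are concatenated in session
order into the 360 × 7 feature matrix.

## Labels

The eight survey answers are expanded to one target per epoch by
interpolation, on the hypothesis that affect changes smoothly over short
spans. Four schemes are provided: linear, pchip (shape-preserving cubic
Hermite), cubic spline and nearest-knot. The spline uses natural boundary
conditions (unspecified in the protocol); interpolated values are clipped to
the 1–5 scale, which only the spline can overshoot; at an exact midpoint
between knots, nearest takes the later knot.

Survey instants map onto the epoch timeline as `floor(t / 2 s)`, clamped
into the survey's phase, giving knots 0, 60, 120, 179, 225, 270, 329, 359.
Two placements are genuinely underdetermined by the protocol and are
documented package choices: T1 is answered at the end of the *discarded*
initial rest and is anchored to the first processed epoch; end-of-phase
surveys (T4, T7, T8) are anchored to the last epoch of their phase, since a
survey cannot index past the data it describes.

The **test set** is the eight knot epochs — the answers the participant
actually gave; the **training set** is the remaining 352 epochs, whose
targets are interpolated. The split is a partition: no epoch is in both.

## Models

Four regressor families are tuned per participant by exhaustive grid search
with 5-fold cross-validation (mean squared error) on the training rows only:

| family | grid | size |
|---|---|---|
| ridge | polynomial degree {1,2,3} × penalty {1e-4 … 1e2} | 18 |
| random forest | trees {100,200,300} × mtry {5,6,7} × depth {6,7} | 18 |
| MLP | layers {1,2} × neurons {3,4} × {relu,tanh} × penalty {1e-3,1e-2,1e-1} | 24 |
| SVR | kernel {linear,poly,rbf,sigmoid} × cost {2^-5 … 2^3} × ε {1e-3,1e-2,1e-1} | 60 |

Design notes, where the protocol leaves the implementation open:

* **Scaling.** Feature columns are standardized with training-row statistics
  only, applied to all rows; the test rows never influence the transform,
  the fold assignment or the selection. (Whether the original analysis
  scaled before or after isolating the training rows is ambiguous;
  training-only scaling is the leakage-free reading.)
* **CV scoring and folds.** The CV criterion is mean squared error
  (consistent with the MSPE evaluation metric's numerator). Folds are
  contiguous, unshuffled blocks of training rows — fully deterministic; a
  seeded shuffle is available via `cv_shuffle`.
* **Ridge.** "Polynomial degree" is implemented as full polynomial feature
  expansion (all monomials up to the degree over the 7 columns) followed by
  a closed-form ridge solve with unpenalized intercept — the only reading
  under which degree is a ridge hyperparameter.
* **Random forest** fits use `ranger`, which exposes the maximum-depth
  hyperparameter directly. Two implementation notes: `ranger` interprets
  seed 0 (the pipeline default) as "unseeded", so the pipeline passes
  `seed + 1`; and during CV the scores of the nested tree counts
  {100,200,300} at fixed (mtry, depth) are read off a single 300-tree
  forest per fold — its first *n* trees are a valid seeded *n*-tree forest —
  and the selected combination is refit with its exact tree count.
* **MLP.** No installed R package offers two hidden layers with relu/tanh
  and an L2 penalty, so the network is implemented in-package and trained by
  L-BFGS with analytic backpropagation gradients, seeded Glorot-uniform
  initialization, and an iteration cap of 100 (the 3–4-neuron networks
  converge well within it; the cap, solver and tolerance are recorded in the
  configuration). Non-convergence is surfaced, not fatal.
* **SVR** uses `e1071` (libsvm), kernels mapped 1:1, other knobs at library
  defaults.
* A hyperparameter combination whose fit errors is scored as worst rather
  than aborting the search; if the final refit itself degenerates (e.g. SVR
  on a constant target has no support vectors), a constant-mean model is
  substituted so the pipeline always yields finite predictions.
* Everything stochastic takes the single pipeline seed (default 0, matching
  the protocol's reproducibility note). Test predictions are reported
  unclipped by default (clipping to 1–5 is available but the original
  analysis shows none).

## Evaluation

Two scores per participant and model, on the eight test surveys:

* **MSPE** `= mean((y_test − y_pred)^2) / mean(y_test) × 100`. The formula
  is implemented exactly as printed — the mean squared error normalized by
  the *mean* (not squared mean) of the true targets — even though its units
  are irregular (it scales linearly under joint rescaling of both arrays);
  the original headline numbers were produced by this definition. The
  conventional normalization by the squared mean is available behind
  `denominator = "mean_squared"`.
* **R²**, the square of the Pearson correlation between truth and
  prediction (per the protocol's own parenthetical), not the coefficient of
  determination (available via `type = "cod"`). Constant inputs yield `NA`
  with a warning, never a silent 0.

Cohort aggregation reports mean ± SEM (sample SD over √n; the protocol's
figure captions name SEM, so SEM is used throughout and labeled) for every
regressor × interpolation cell, identifies the best cell by minimum mean
MSPE, and profiles that cell's mean absolute error per survey T1–T8.

## The synthetic session generator

No recordings are distributed with the original study, so the generator
emulates its acquisition conditions and is itself first-class, tested code:

* **Ground-truth trajectory**: piecewise linear through anchors — low at
  session start (1.2–2.2), peak at the end of the MIST test (4.2–5), decay
  through relaxation (to 1.4–2.2) and slightly further through rest —
  sampled at epoch midpoints. The anchor family matches the qualitative
  published trajectories (monotone rise to a T4 peak, then decay) without
  inventing participant data; anchors are drawn per seed, or can be fixed.
* **EEG**: per channel, a sum of band-limited Gaussian noise components
  (white noise with the out-of-band spectrum zeroed — the simplest generator
  with controllable band power) whose per-band variance follows
  `baseline × (1 + coupling × normalized stress)`. Default baselines give a
  ~9–10 μV RMS background; default couplings raise Gamma (+1.5) and Beta
  (+0.8) and depress Alpha (−0.4) and Theta (−0.2) with stress, the
  direction the relative-gamma and alpha stress markers assume. Because
  every epoch is standardized downstream, only this *differential* coupling
  survives preprocessing — a deliberate property: the features carry
  spectral shape, not amplitude.
* **Nuisance terms**: a 50 Hz mains sinusoid (20 μV, random phase per
  channel); sporadic artifact bursts (150 μV raised-cosine-windowed 10 Hz
  bursts, probability 0.02 per epoch, one random channel, confined to the
  central half of their epoch so filtering cannot smear them across epoch
  boundaries) — these must exceed the 75 μV threshold and are recorded in
  the ground truth so tests can assert exact recovery; survey reporting
  noise (±1 with probability 0.1, then clipped to 1–5); and ±3 s uniform
  recording-length jitter, emulating the manually marked onsets and
  exercising the resampling stage. Generated lengths are snapped to the
  nearest FFT-friendly sample count (largest prime factor ≤ 127, a ≲0.2 s
  adjustment) so the mixed-radix FFTs stay fast for every seed.
* **What it does not model** (hence what passing tests do not show about
  real data): cortical source geometry, eye-blink/EMG artifact morphology,
  inter-channel covariance, non-stationarities beyond the stress coupling,
  or ordinal reporting biases beyond symmetric ±1 jitter. Synthetic
  performance numbers characterize the pipeline, not human EEG; the
  original cohort's headline scores are not reproducible without the
  undeposited recordings.

## Problem sizes and runtime

The default configuration mirrors the study: 23 participants, 4 regressor
families × 4 interpolation methods, full grids, 5-fold CV — roughly 66,000
model fits — and completes in on the order of ten minutes on one CPU. The
test suite uses this full cohort once, a 5-participant strong-coupling
cohort for the recovery property, and reduced grids elsewhere.

## Known limitations

* The MSPE's irregular units are inherited deliberately; compare values only
  against scores computed with the same definition.
* The ridge polynomial expansion at degree 3 creates 119 regressors from 7
  features; with 352 training rows this is well-posed but the penalty grid's
  small values can select near-interpolating fits on very smooth traces.
* The per-survey mapping of T1 (answered before the processed timeline
  begins) to epoch 0 is a convention; alternative anchorings would shift one
  test point.
* `interpolate_spsl` accepts any knot count ≥ 2, but the protocol's split
  semantics (352/8) assume the nominal 8-survey schedule.
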