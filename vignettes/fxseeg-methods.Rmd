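---
title: "Methods: EEG variables, simulators and the classification protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG variables, simulators and the classification protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fxseeg)
```

`fxseeg` implements an EEG biomarker workflow for separating Fragile X
Syndrome (FXS) from typically developing controls (CON): resting-state
spectral variables, auditory-chirp time-frequency variables, a Gaussian
naive Bayes classifier built from scratch, and an evaluation protocol of
70/30 holdout AUC, full-dataset AUC and 10-fold cross-validation. Because
per-subject human recordings of this kind are access-restricted, the
package also ships two simulators with known ground truth — one at the
feature level, one at the signal level — so that every stage of the
pipeline is testable against analytic expectations.

## Resting spectral variables

A resting recording is represented as an `epoched_recording`: a
channels × epochs × samples array with a sampling rate and channel labels.
`amplitude_spectrum()` applies a Hann window to each 2 s epoch, takes the
FFT, and scales by `2 / sum(window)` so that a sinusoid of amplitude *A*
lands in its frequency bin with value *A*. Two-second epochs give the
0.5 Hz resolution the band definitions assume; other epoch lengths are
rejected rather than silently regridded. Amplitude (not power) spectra are
averaged over epochs, then over the channels of each scalp region
(frontal, posterior, whole head).

Seven bands are analyzed (Hz, lower edge inclusive): delta 1–4, theta 4–8,
alpha1 8–10, alpha2 10–13, beta 13–30, gamma1 30–55, gamma2 65–90. The
55–65 Hz gap avoids mains interference and is excluded from the relative
denominator, so relative band values over a region sum to exactly 1.
Absolute power is the band amplitude sum expressed on a picovolt scale
(×10⁶). Peak alpha frequency (PAF) is the raw arg-max of log power on the
0.5 Hz grid within 6–14 Hz — no spectral detrending or curve fitting —
with ties broken toward the lower frequency and a warning when the maximum
sits on the window edge (a sign that theta or beta activity, not an alpha
rhythm, dominates the window). Per region this yields 7 absolute + 7
relative + 1 PAF variables; over three regions, 45 named variables.

## Chirp time-frequency variables

Chirp trials are analyzed on a fronto-central electrode cluster average
with Morlet wavelets (`morlet_transform()`), default 2–100 Hz in 1 Hz
steps, with the cycle count rising linearly from 1 at the lowest to 30 at
the highest analyzed frequency. Wavelets are amplitude-normalized so a
sinusoid of amplitude *A* produces coefficients of modulus *A*; samples
within three Gaussian SDs of an epoch edge are marked invalid (`NA`).
Coefficients are stored on a decimated 10 ms time grid, which changes
nothing statistically (ITPC and mean power are pointwise statistics) and
keeps the coefficient cube small.

Two statistics are computed across trials at every time-frequency point:

* **ITPC** — the plain resultant length of the unit phase vectors,
  `|mean(coef / |coef|)|`, in [0, 1]. No bias correction or Rayleigh
  transform is applied; the finite-trial floor for N random-phase trials
  is √π/(2√N) and is accounted for where it matters (tests, null bounds).
* **Single-trial power (STP)** — `10·log10` of the trial-mean squared
  modulus (decibels). "Evoked alpha" is STP baseline-corrected by
  subtracting the per-frequency mean log power of the pre-stimulus
  baseline, so stationary activity maps to 0 dB and post-onset alpha
  desynchronization is negative.

Seven regions of interest give the chirp variables: broadband gamma,
theta and baseline-corrected alpha STP; ITPC along the ±10 Hz diagonal
band following the 50 Hz/s sweep in its low-gamma (30–50 Hz) and
high-gamma (70–90 Hz) segments; and onset/offset ITPC in the 4–13 Hz
range just after stimulus onset and offset.

## The classifier and the evaluation protocol

`nbc_fit()` is a Gaussian naive Bayes classifier written directly from
its definition: per class and per feature, a mean and an unbiased (n−1)
variance; class priors fixed at 0.5 regardless of the sample composition,
because the clinical question is diagnosis under equal prior odds.
Posteriors are computed in log space with a log-sum-exp normalization;
near-zero variances are floored (with a warning) at
`max(1e-12, 1e-9 × pooled variance)`; an exact posterior tie predicts
CON. The implementation is validated against an independent reference
(`e1071::naiveBayes`) which is used only as an oracle in tests, never as
the implementation.

`evaluate_variable_set()` applies the full protocol to one named variable
set: a stratified 70/30 split (per class, the training count is
`floor(n × 0.7 + 0.5)`), AUC of the posterior on the holdout; AUC and a
0.5-threshold confusion matrix on the entire dataset after refitting; and
stratified 10-fold cross-validated classification error (folds are
reduced, with a warning, if a class cannot fill ten folds). AUC is
computed by the rank statistic with ties counted one half, which equals
the trapezoidal area under the empirical ROC exactly; `pROC` serves as a
second oracle in the tests.

`run_full_study()` evaluates all a-priori variable sets — 25 each for
absolute and relative power (three regions × seven bands plus region and
global composites), 4 for PAF, 11 for chirp — then re-runs the top two
sets per family (by full-dataset AUC, CV error and name as tie-breaks) on
the male, female and non-mosaic-male subgroups. Absolute power is excluded
from subgroup analysis by default because its within-sex scale differences
make cross-study comparison unreliable. A final stage extracts resting
features from a signal-level mini-cohort reduced to the standard
20-channel clinical montage (nearest-sensor selection from the dense
array, no interpolation) to ask whether the spectral biomarkers survive
clinical-grade spatial sampling. Every stage derives its RNG stream from
the config seed via `derive_seed()`, so reports are bit-identical across
runs.

## Simulators: what they emulate and what they do not

**Feature-level** (`simulate_feature_table()`): each participant's
variables are drawn independently from the class-conditional Gaussian
(mean, SD) of the bundled cohort statistics (`cohort_stats()`), which
tabulate FXS/CON and sex/mosaicism subgroup cells for all 52 variables.
Bounded variables (relative power, ITPC) are clipped to [0, 1];
`clipped_normal_mean()` gives the exact expectation of the clipped draw,
which differs from the nominal mean by a known, testable bias when the
mean sits within a few SDs of a bound. This generator matches the naive
Bayes model assumptions *by construction*, with one deliberate
consequence: real EEG variables are strongly correlated within a family,
so composite sets ("All Variables") classify far better on simulated
tables than they could on real data. Simulated AUCs validate the
machinery and preserve published effect *directions*; their magnitudes
for multi-variable sets should not be read as clinical estimates.

**Signal-level** (`simulate_resting_eeg()`, `simulate_chirp_trials()`):
resting channels are 1/f pink noise (FFT spectral shaping) plus sinusoidal
oscillators — including an alpha oscillator whose frequency is the ground
truth for PAF recovery — plus white noise; defaults are 20 s at 1000 Hz.
Chirp trials contain damped 6 Hz onset/offset transients, a
chirp-following oscillation whose instantaneous frequency rises at
50 Hz/s with per-trial wrapped-normal phase jitter (one knob controlling
all ITPC variables), an alpha oscillator attenuated after onset (producing
negative evoked alpha), and white noise. The simulators make no attempt at
realistic spatial topography, artifacts, or non-stationarity; channels are
exchangeable within a region. They exist to give round-trip tests a known
truth: generator alpha frequency → PAF (exact on the 0.5 Hz grid), theta
amplitude → relative theta (monotone), jitter SD → ITPC (monotone
decreasing, Spearman ρ = −1).

## Numerical and design decisions

* Spectra are averaged as amplitudes, not powers, before band summation;
  the picovolt scale (×10⁶) matches the reporting convention of the
  tabulated statistics.
* The dB convention is `10·log10` of squared modulus throughout.
* ITPC is the uncorrected resultant length; null levels are handled by
  explicit analytic bounds rather than bias-corrected estimators.
* Stratified split sizes round to nearest per class (so 70 FXS / 71 CON
  yields a 49 + 50 training set), keeping both classes within one subject
  of the target fraction.
* Problem sizes in examples and the default study config — cohort
  compositions of 141 resting and 114 chirp participants, 20 subjects per
  group and 20 s per recording in the montage mini-cohort — are this
  package's own choices, sized so the full study completes in seconds
  while keeping Monte-Carlo error well inside test tolerances.
* Derived seeds are hashed into `[0, 2³¹)` so every stage is independently
  reproducible from one integer.

## A worked example

```{r example, eval = FALSE}
cfg <- study_config(seed = 1)
study <- run_full_study(cfg)
print(study)
write_study_report(study, "results/study")
```

See the numbered scripts under `analysis/` for the full workflow:
cohort simulation, resting and chirp signal-level feature extraction, and
the complete classification study.
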