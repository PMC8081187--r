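---
title: "Decoding two-class tactile P300 responses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding two-class tactile P300 responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

tactileP300 implements the complete analysis chain for a two-class tactile
brain-computer interface built on the oddball principle: rare target
stimuli (100 Hz carrier, 150 ms) are embedded among frequent disturbance
stimuli (23 Hz, 200 ms, 400 ms inter-stimulus interval) delivered to the
left or right index finger, and the attended side is decoded from the EEG.
This vignette explains the models the package implements, the tunable
parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical decisions taken where the design was open.

## The paradigm and its timing

A run is eight blocks of 13 trials; each trial presents six stimuli, of
which exactly one (drawn uniformly among the six slots) is a target —
except the first trial of each block, which is all disturbances and marks
the block start. Only one site is stimulated within a block, and the
subject attends that hand. A target trial therefore lasts

```
target_dur + 5 * disturb_dur + 5 * isi = 150 + 1000 + 2000 = 3150 ms,
```

counting only the between-stimulus gaps. Whether a trailing interval
belongs to the trial is a convention; we adopt the five-gap reading
because it reproduces the protocol's stated 3.15 s exactly, and expose a
separate `inter_trial_gap` (default 0 ms) for anything beyond it. Onsets
are integer milliseconds, so at the 1,000 Hz sampling rate every event
falls exactly on a sample. "Pseudorandom" target placement is a seeded
uniform draw per trial with no constraint on consecutive placements; the
attended side alternates left, right, left, ... across blocks unless an
explicit order is given. All of these are configurable in
`paradigm_config()`.

The protocol's 1-minute inter-block break is the default, but simulated
runs in the tests and examples use a 1 s break: a synthetic break carries
no signal, and the shorter gap keeps one run at roughly 335 s x 30
channels of samples.

## The synthetic forward model

`simulate_run()` realizes a deliberately simple forward model with planted
ground truth, so that every downstream stage can be checked by parameter
recovery rather than by eye:

* **P300.** A raised-cosine (Hann) bump of full width 300 ms peaking
  exactly 350 ms after each *attended* target onset, mixed through a
  centro-parietal topography (maximal at Cz/CP1/CP2/Pz). Ignored targets
  and disturbances receive nothing. The raised cosine was chosen over,
  say, a Gaussian because its peak, width and support are closed-form,
  which makes latency- and topography-recovery tests exact. The default
  peak amplitude is 5 µV against 5 µV of background noise — a
  realistic single-trial SNR that still yields a clean average over ~50
  trials per class.
* **Lateralized oscillatory contrast.** Two band-limited (8–20 Hz)
  sources over the left and right central channels (C3- and C4-peaked);
  in left-attended blocks the right-hemisphere source runs at
  `lateral_power_ratio` times the variance of its counterpart, and vice
  versa. This is the class-dependent structure that CSP is designed to
  extract. The default ratio of 4 gives cross-validated accuracies in the
  mid-90s on one run — the regime the method targets.
* **Background.** Independent per-channel 1/f noise (`noise_exponent`
  1, per-channel SD `noise_scale` = 5 µV), generated by FFT shaping so
  the spectral slope is exact by construction.
* **Blinks** (off by default): sparse 350 ms frontal bumps
  (Fp1/Fp2-dominated, ~80 µV, log-normal amplitude jitter) at a
  configurable rate, included solely to exercise ocular-artifact removal.

What the generator does **not** emulate, and what passing tests therefore
do not show: steady-state somatosensory responses to the 23/100 Hz
carriers (they fall essentially outside the 4–20 Hz classification band),
heavy-tailed non-Gaussian background dynamics (real alpha bursts etc.),
non-stationarity across blocks, electrode drift or line noise, and
between-subject variability. Results on this generator validate the
*pipeline machinery*, not clinical performance.

## Preprocessing

The fixed analysis order is: re-reference to the mastoid average
(TP9/TP10) → 0.5–30 Hz band-pass → optional ICA ocular cleanup → epoch
−200..+1000 ms around target onsets → subtract the −200..0 ms baseline
mean. An ECG channel, when present, is dropped first. Epoch windows are
inclusive at both ends at sample resolution (1201 samples at 1,000 Hz);
time 0 is the onset sample; events whose window leaves the recording are
dropped with an exact count.

**Filter realization.** The nominal filter is a 4th-order Butterworth
band-pass, applied forward-backward ("zero-phase") so ERP latencies are
not shifted; a causal single-pass mode exists for real-time emulation.
Internally each band-pass is a cascade of a 4th-order high-pass and a
4th-order low-pass: a direct transfer-function band-pass is numerically
unstable at the narrow normalized bands this pipeline needs (0.5–3 Hz at
1,000 Hz puts poles on top of each other near z = 1; the filtered output
diverges), while the cascaded sections are stable with passband ripple
under 1%. Each signal is demeaned before filtering, which shortens edge
transients inside short epochs. Narrow bands (e.g. alpha, 8–13 Hz) retain
~75–80% of mid-band amplitude after the forward-backward pass; since CSP
features are variance *ratios*, this common attenuation cancels.

**Ocular artifact removal.** The expert screening of ICA components
usual in ERP practice is automated as a two-threshold rule: flag a component when
(a) at least 60% of its squared topography lies on the frontal channels
and (b) at least 75% of its spectral power lies below 3 Hz. The second
threshold was placed by measurement: on a 1/f background, *any*
component already has roughly 45–65% of its power below 3 Hz, so a 50%
cut flags clean components, whereas planted blink components measure
above 90%. Both thresholds, the frontal set and the band edge are
arguments.

The decomposition itself is deflationary FastICA (tanh contrast after PCA
whitening). Deflation rather than the symmetric variant is a consequence
of the generator: ICA can only identify non-Gaussian directions, and in a
Gaussian subspace the FastICA fixed-point update is pure sampling noise,
so a symmetric sweep over all 30 components of a mostly-Gaussian
recording never settles. Deflation extracts the non-Gaussian components
(blinks first — they are sparse and heavily super-Gaussian) and, when a
component stops converging, keeps the remaining orthogonal subspace
unrotated; since independence is rotation-invariant in a Gaussian
subspace, any basis of it is an equally valid completion.
`strict_convergence = TRUE` turns non-convergence into an error with
iteration diagnostics instead. Unmixing is estimated on 4x-decimated data
(estimation only; cleanup runs at full rate), and recordings shorter than
30 s are refused.

## Spectral analysis and band selection

`welch_psd()` is a Hann-windowed averaged periodogram with density
normalization (the one-sided PSD integrates to the signal power; tests
check Parseval within 5%). `ersp()` and `itc()` use complex Morlet
wavelets, 7 cycles, on a linear 2–30 Hz grid by default — a conventional
compromise between time and frequency resolution at these frequencies;
the cycle count and grid are arguments. ERSP is expressed as
`10*log10(P / P_baseline)` against the −200..0 ms window, making it
scale-invariant; ITC is the magnitude of the mean unit-normalized
coefficient, 1 for perfect phase locking and ~`sqrt(pi/4)/sqrt(n)` for n
phase-random trials.

The band filter bank splits epochs into delta (0.5–3), theta (4–7), alpha
(8–13) and beta (14–20 Hz). Beta is capped at 20 Hz because task
information is concentrated below 20 Hz; the classification band
combining theta through beta is 4–20 Hz. `band_contribution()` scores
each band by running the full CSP + classifier cross-validation on
band-filtered epochs; bands that do not beat the 0.5 chance level of this
balanced two-class problem are discarded (`select_bands()`), which is the
rule that removes delta.

## Common Spatial Patterns

For class covariances `S_A`, `S_B` (left- vs right-attended), CSP solves
the generalized eigenproblem `S_A w = lambda (S_A + S_B) w` by whitening
the composite covariance and rotating by the eigenvectors of the whitened
`S_A`. Rows of the resulting projection `W` (spatial filters) are ordered
by `lambda` — the fraction of composite variance each filtered signal
carries under class A — and the `m` filters from each end are kept, the
directions with the most extreme variance ratios. Columns of `W^-1` are
the corresponding scalp patterns. Each epoch `E` then yields the
log-variance feature vector

```
x_p = log( var(w_p E) / sum_i var(w_i E) ),   p = 1..2m,
```

which is scale-invariant and, being a log proportion, non-positive.

Numerical and design choices:

* **Per-epoch trace normalization** before averaging, so every trial
  contributes equally regardless of broadband power.
* **Shrinkage.** With 30 channels and ~1,000-sample epochs the class
  covariances are noisy; a Ledoit-Wolf-style intensity computed from the
  across-trial dispersion of per-epoch covariances shrinks toward a
  scaled identity (`shrinkage = "auto"`, or any fixed value; 0 disables
  it, which the closed-form tests use).
* **m = 3 by default** (6 filters, 6 features), matching the six spatial
  patterns typically reported for this task; `m` is an argument (e.g. 6
  for 12 filters) since "the largest and smallest six" can be read either
  way.
* **Sign convention:** each filter is scaled so its largest-magnitude
  pattern coefficient is positive, ties broken toward the lowest channel
  index, making fits deterministic up to nothing.
* **Natural log** in the features; any other base is a monotone affine
  rescaling that linear classifiers ignore.
* CSP is fit on the 4–20 Hz filtered, 0–1,000 ms post-onset portion of
  attended-target epochs.

## Classification and evaluation

LDA is the primary classifier, implemented from its closed form (pooled
within-class covariance, `w = S^-1 (mu_1 - mu_0)`, boundary at the
projected midpoint under equal priors) with an identity-shrinkage
fallback when the pooled covariance is singular. An RBF-kernel SVM at
cost 0.4 is available as an alternative; its kernel width defaults to
`1/(d * mean feature variance)` since only the cost was prescribed.

Cross-validation is stratified 10-fold (stratification protects the small
per-class counts; plain k-fold could starve a fold). Folds are assigned
within each class on *sorted epoch ids* with a seeded shuffle, so the
result is invariant to epoch order. CSP filters and the classifier are
re-fit inside every training fold — the band-pass applied beforehand has
no data-dependent parameters, so per-epoch filtering is fold-safe, which
tests verify by corrupting held-out epochs and hashing the fitted
training-fold models. Chance is exactly 0.5 in this balanced design.

`sliding_window_eval()` repeats the cross-validation on successive
post-onset windows (500 ms long, 100 ms steps by default; a 0–1,000 ms
epoch gives 6 windows), emulating the latency/accuracy trade-off of a
real-time decoder.

## Information transfer rate

`bits_per_trial()` implements the Wolpaw formula
`B = log2 N + P log2 P + (1-P) log2((1-P)/(N-1))` with the continuity
convention `0 log 0 = 0`; at N = 2 it is one minus the binary entropy of
P. `itr()` multiplies by M decisions per minute. M defaults to 9.5238 —
the protocol's value, equivalent to 6.3 s per decision — but is left a
free parameter rather than derived, because the mapping from 3.15 s
trials to decisions is a protocol convention, not an algebraic
consequence. One published operating point (9.09 bits/min at 98.5%
accuracy) is inconsistent with the formula (which gives 8.45 at
M = 9.5238) and is deliberately not reproduced; all other printed values
(9.52, 4.91, 3.37, 6.75, 6.88 bits/min) follow exactly. Internally ITR is
kept at full precision and rounded only for presentation.

## Problem sizes and degenerate inputs

The test suite and examples run one synthetic run per condition: 8 blocks
x 13 trials = 96 attended-target epochs at 30 channels x 1,201 samples,
with smaller runs (2–4 blocks, sometimes 500 Hz) for unit-level checks
and 1,000-draw Monte Carlo for the ITC null. Degenerate inputs are
contracts, not accidents: epochs with zero projected variance, single
classes, `2m` exceeding the channel count, band edges at or above
Nyquist, windows outside epochs, truncated binary payloads and unknown
configuration keys all raise named errors; a single-epoch ITC warns that
it is identically 1; identical vectors in the paired t test return t = 0,
p = 1, while a zero-variance non-zero shift is an error.

## Known limitations

Beyond the generator simplifications above: the BrainVision reader
supports only the dialect the pipeline writes (MULTIPLEXED orientation,
IEEE_FLOAT_32/INT_16, marker format 1) and rejects others loudly;
IEEE_FLOAT_32 is single precision, so round-trips are bit-exact only for
values representable in 32-bit floats; the automated EOG rule stands in
for expert component inspection and has only been validated against the
generator's blink model; and the sliding-window evaluator re-runs full
cross-validation per window, which is faithful but quadratic in the
number of windows times folds.
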