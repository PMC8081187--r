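# tactileP300

An R package for simulating and decoding **two-class tactile P300
brain-computer interfaces (BCIs)**. Tactile BCIs target users for whom
visual or auditory interfaces are impractical — people with locked-in
syndrome, ALS, or stroke — by delivering stimulation to the fingertips
and reading the intention ("left hand" vs "right hand") from the EEG.
The paradigm is an oddball design: rare *target* stimuli (100 Hz carrier,
150 ms) are interleaved among frequent *disturbances* (23 Hz, 200 ms,
400 ms gaps), six stimuli per trial, 13 trials per block, eight blocks
per run, with only one hand stimulated per block. Attending the rare
target evokes a P300 — a centro-parietal positivity peaking near 350 ms —
and the attended side additionally modulates lateralized oscillatory
power over the central channels.

The package provides the full chain, testable end-to-end on synthetic
data with planted ground truth:

* **Paradigm** — exact stimulus schedules with seeded pseudorandom
  target placement (`paradigm_config()`, `generate_schedule()`).
* **Synthesis** — 30-channel, 1,000 Hz EEG with a planted raised-cosine
  P300, class-dependent 8–20 Hz lateralized variance, 1/f background
  and optional blinks (`simulate_run()`).
* **I/O** — BrainVision `.vhdr/.vmrk/.eeg` reading and writing
  (MULTIPLEXED, `IEEE_FLOAT_32`/`INT_16`) and tab-separated event tables.
* **Preprocessing** — zero-phase 4th-order Butterworth band-pass,
  mastoid re-referencing, epoching with baseline correction, and
  ICA-based ocular artifact removal (`bandpass()`, `rereference()`,
  `epoch_recording()`, `remove_eog()`).
* **Spectral analysis** — Welch PSD, Morlet ERSP and inter-trial
  coherence, and a delta/theta/alpha/beta filter bank with per-band
  classification scoring (`welch_psd()`, `ersp()`, `itc()`,
  `band_contribution()`).
* **CSP + classification** — Common Spatial Patterns with log-variance
  features, LDA (or RBF-SVM, C = 0.4), stratified 10-fold
  cross-validation and sliding-window evaluation (`fit_csp()`,
  `crossval()`, `sliding_window_eval()`).
* **Metrics** — grand-average ERPs, paired t tests, and the Wolpaw
  information transfer rate (`grand_average()`, `itr()`).

## The model in brief

CSP simultaneously diagonalizes the two class covariances: it solves
`S_A w = λ (S_A + S_B) w`, orders the spatial filters (rows of `W`, with
`Z = W E` for an epoch `E`) by the class-A variance ratio `λ ∈ [0, 1]`,
and keeps the `m` most extreme filters from each end. Each epoch is
summarized by the log-variance proportions

```
x_p = log( var(Z_p) / Σ_i var(Z_i) ),  p = 1..2m,
```

classified with LDA. Decoding accuracy `P` converts to bits per decision
via the Wolpaw formula

```
B = log2(N) + P·log2(P) + (1−P)·log2((1−P)/(N−1)),   ITR = B·M,
```

with `N = 2` classes and `M = 9.5238` decisions/min (one 3.15 s trial
per decision).

## Worked example

Simulate a small run (4 blocks, 500 Hz, 1 s breaks), run the whole
pipeline, and read the report:

```r
library(tactileP300)

cfg <- pipeline_config(
  paradigm  = list(trials_per_block = 6, blocks_per_run = 4,
                   inter_block_break = 1),
  generator = list(fs = 500),
  cv        = list(k = 5)
)
report <- run_pipeline(cfg, seed = 42)
report
#> <pipeline_report> seed 42: 20 attended-target epochs
#>   per-band accuracy: delta=0.450, theta=0.500, alpha=0.700, beta=0.950
#>   combined 4-20 Hz: 0.900 +/- 0.137; ITR 5.06 bits/min
```

Reading the report: the delta band classifies at chance (0.45) and is
dropped by the band-selection rule, the alpha and beta bands carry the
lateralized class information, and the combined 4–20 Hz CSP(m=3)+LDA
model reaches 90% cross-validated accuracy, worth 5.06 bits/min at one
decision per 6.3 s. ITR at any accuracy is a one-liner:

```r
round(itr(c(0.835, 0.895, 0.95, 1.0), N = 2, M = 9.5238), 2)
#> [1] 3.37 4.91 6.80 9.52
```

Each result type has `tidy()`/`glance()` and `autoplot()` methods
(per-fold accuracies, ERP ribbons, time-frequency rasters, sliding-window
profiles), and `inst/scripts/p300_pipeline.R` exposes
`simulate` / `evaluate` / `itr` subcommands for shell use.

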