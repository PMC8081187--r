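#' Welch power spectral density
#'
#' Averaged periodogram over Hann-windowed, overlapping segments, with
#' density normalization: the one-sided PSD integrates (sums times the
#' frequency step) to the signal power, so Parseval's relation holds up to
#' windowing loss.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz.
#' @param segment_len Segment length in samples (default: `length(x)/8`,
#'   at least 64, at most `length(x)`).
#' @param overlap Fractional overlap between segments (0 to <1).
#' @return A tibble with columns `freq` (Hz) and `psd` (power per Hz),
#'   class `welch_psd`.
#' @export
welch_psd <- function(x, fs, segment_len = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(segment_len)) segment_len <- min(n, max(64, floor(n / 8)))
  if (segment_len > n) abort("`segment_len` exceeds the signal length")
  segment_len <- as.integer(segment_len)
  hop <- max(1L, as.integer(floor(segment_len * (1 - overlap))))
  starts <- seq(1L, n - segment_len + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(segment_len) / (segment_len + 1))) # Hann
  u <- sum(w^2)
  half <- floor(segment_len / 2)
  acc <- numeric(half + 1)
  for (s0 in starts) {
    seg <- x[s0:(s0 + segment_len - 1)] * w
    sp <- abs(fft(seg))^2
    acc <- acc + sp[seq_len(half + 1)]
  }
  psd <- acc / (length(starts) * fs * u)
  # one-sided: double everything except DC (and Nyquist for even lengths)
  dbl <- rep(2, half + 1)
  dbl[1] <- 1
  if (segment_len %% 2 == 0) dbl[half + 1] <- 1
  out <- tibble(freq = (0:half) * fs / segment_len, psd = psd * dbl)
  class(out) <- c("welch_psd", class(out))
  out
}

# complex Morlet wavelet transform of one channel: epochs x freqs x times
morlet_transform <- function(epochs, channel, freqs, cycles = 7) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.character(channel)) channel <- match(channel, epochs$channel_names)
  if (is.na(channel)) abort("unknown channel")
  fs <- epochs$fs
  if (max(freqs) >= fs / 2) abort("wavelet frequency at or above the Nyquist frequency")
  n_ep <- dim(epochs$data)[1]
  n_smp <- dim(epochs$data)[3]
  wavelets <- lapply(freqs, function(f) {
    sd_t <- cycles / (2 * pi * f)
    half <- ceiling(3.5 * sd_t * fs)
    t <- (-half:half) / fs
    wv <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sd_t^2))
    wv / sqrt(sum(Mod(wv)^2))
  })
  max_wv <- max(vapply(wavelets, length, 1L))
  nfft <- 2^ceiling(log2(n_smp + max_wv - 1))
  wv_f <- lapply(wavelets, function(wv) fft(c(wv, rep(0, nfft - length(wv)))))
  out <- array(0i, dim = c(n_ep, length(freqs), n_smp))
  for (ep in seq_len(n_ep)) {
    xf <- fft(c(epochs$data[ep, channel, ], rep(0, nfft - n_smp)))
    for (k in seq_along(freqs)) {
      conv <- fft(xf * wv_f[[k]], inverse = TRUE) / nfft
      lag <- (length(wavelets[[k]]) - 1) / 2
      out[ep, k, ] <- conv[(lag + 1):(lag + n_smp)]
    }
  }
  out
}

timefreq_map <- function(values, freqs, times, kind) {
  out <- tidyr::expand_grid(freq = freqs, time_ms = times)
  out$value <- as.vector(t(values)) # values is freqs x times
  attr(out, "kind") <- kind
  class(out) <- c("timefreq_map", class(out))
  out
}

#' Event-related spectral perturbation
#'
#' Time-frequency power (complex Morlet wavelets, 7 cycles by default)
#' averaged over epochs and expressed in dB relative to the mean
#' pre-stimulus baseline power at each frequency:
#' `10 * log10(P(f, t) / P_baseline(f))`. Scaling the signal leaves the
#' map unchanged; epochs statistically identical to their baseline give
#' ~0 dB everywhere.
#'
#' @param epochs An [epoch_set()] with at least 2 epochs.
#' @param channel Channel name or index.
#' @param freqs Analysis frequencies in Hz.
#' @param baseline_window Baseline window in ms (default the pre-stimulus
#'   part of the epoch).
#' @param cycles Wavelet width in cycles.
#' @return A `timefreq_map` tibble (`freq`, `time_ms`, `value` in dB).
#' @export
ersp <- function(epochs, channel, freqs = 2:30,
                 baseline_window = c(epochs$tmin, 0), cycles = 7) {
  if (dim(epochs$data)[1] < 2) abort("ERSP needs at least 2 epochs")
  tfc <- morlet_transform(epochs, channel, freqs, cycles)
  power <- apply(Mod(tfc)^2, c(2, 3), mean) # freqs x times
  times <- epoch_times(epochs)
  bidx <- which(times >= baseline_window[1] - 1e-9 &
                  times <= baseline_window[2] + 1e-9)
  if (length(bidx) == 0) abort("baseline window contains no samples")
  base <- rowMeans(power[, bidx, drop = FALSE])
  timefreq_map(10 * log10(power / base), freqs, times, "ERSP")
}

#' Inter-trial coherence
#'
#' Phase-locking across epochs: the magnitude of the mean of unit-
#' normalized Morlet coefficients, `|mean_k F_k(f,t) / |F_k(f,t)||`,
#' in `[0, 1]`. Identical epochs give 1 everywhere; for n epochs with
#' independent random phases the expected value is `sqrt(pi/4)/sqrt(n)`.
#' Zero-magnitude coefficients are skipped, with the skip count reported
#' in the `"n_skipped"` attribute; a single epoch trivially gives 1 and is
#' flagged with a warning.
#'
#' @inheritParams ersp
#' @return A `timefreq_map` tibble (`freq`, `time_ms`, `value` in `[0,1]`).
#' @export
itc <- function(epochs, channel, freqs = 2:30, cycles = 7) {
  n_ep <- dim(epochs$data)[1]
  if (n_ep < 1) abort("ITC needs at least 1 epoch")
  if (n_ep == 1) warn("ITC of a single epoch is degenerate (identically 1)")
  tfc <- morlet_transform(epochs, channel, freqs, cycles)
  mag <- Mod(tfc)
  zero <- mag == 0
  phase <- tfc
  phase[!zero] <- tfc[!zero] / mag[!zero]
  phase[zero] <- 0i
  counts <- n_ep - apply(zero, c(2, 3), sum)
  itc_val <- Mod(apply(phase, c(2, 3), sum)) / pmax(counts, 1)
  out <- timefreq_map(itc_val, freqs, epoch_times(epochs), "ITC")
  attr(out, "n_skipped") <- sum(zero)
  out
}

#' Canonical EEG frequency bands
#'
#' The delta/theta/alpha/beta segmentation used by the band filter bank:
#' delta 0.5-3, theta 4-7, alpha 8-13, beta 14-20 Hz. The beta band is
#' capped at 20 Hz, matching the 0.5-20 Hz restriction under which almost
#' all task-related spectral energy falls; the classification band
#' combining theta through beta is 4-20 Hz.
#'
#' @return A tibble with columns `name`, `low`, `high`.
#' @export
band_specs <- function() {
  tibble(name = c("delta", "theta", "alpha", "beta"),
         low = c(0.5, 4, 8, 14), high = c(3, 7, 13, 20))
}

#' Filter an epoch set into frequency bands
#'
#' Applies the fourth-order Butterworth band-pass of [bandpass()] to the
#' broadband epochs once per band, independently (bands are non-adjacent
#' by design, so no sum-of-bands reconstruction is implied).
#'
#' @param epochs An [epoch_set()].
#' @param bands A tibble like [band_specs()].
#' @param order Filter order.
#' @param mode Filtering mode, as in [bandpass()].
#' @return A named list of `epoch_set`s, one per band.
#' @export
band_filter_bank <- function(epochs, bands = band_specs(), order = 4,
                             mode = "zero-phase") {
  stopifnot(inherits(epochs, "epoch_set"))
  out <- lapply(seq_len(nrow(bands)), function(i) {
    bandpass(epochs, bands$low[i], bands$high[i], order = order, mode = mode)
  })
  names(out) <- bands$name
  out
}

#' Per-band classification contribution
#'
#' Scores each frequency band by running the full CSP + classifier
#' cross-validation pipeline on band-filtered copies of the epochs. Bands
#' whose accuracy does not exceed the chance level (0.5 in this balanced
#' two-class design) are the ones the band-selection rule discards; the
#' delta band typically lands there, motivating the 4-20 Hz classification
#' band.
#'
#' @param epochs An [epoch_set()] whose labels contain exactly two attended
#'   classes (see [filter_epochs()]).
#' @param bands A tibble like [band_specs()].
#' @param m CSP filter pairs per extreme.
#' @param classifier `"lda"` or `"svm"`.
#' @param k Cross-validation folds.
#' @param seed Fold-assignment seed.
#' @return A tibble with one row per band: `band`, `low`, `high`,
#'   `accuracy`, `sd`; chance level in the `"chance"` attribute.
#' @export
band_contribution <- function(epochs, bands = band_specs(), m = 3,
                              classifier = "lda", k = 10, seed = 1) {
  if (length(unique(epochs$labels)) < 2) {
    abort("band scoring needs two classes of epochs")
  }
  filtered <- band_filter_bank(epochs, bands)
  rows <- purrr::map2(filtered, seq_len(nrow(bands)), function(eb, i) {
    cv <- crossval(eb, m = m, classifier = classifier, k = k, seed = seed)
    tibble(band = bands$name[i], low = bands$low[i], high = bands$high[i],
           accuracy = cv$mean, sd = cv$sd)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "chance") <- 0.5
  out
}

#' Bands retained by the selection rule
#'
#' @param contribution A [band_contribution()] table.
#' @param chance Chance level (default from the table's attribute).
#' @return The rows whose accuracy exceeds chance.
#' @export
select_bands <- function(contribution, chance = attr(contribution, "chance") %||% 0.5) {
  contribution[contribution$accuracy > chance, ]
}
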