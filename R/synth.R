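#' Synthetic EEG generator parameters
#'
#' Controls the forward model used to simulate a run of the tactile oddball
#' protocol: a P300 deflection added at attended-target onsets through a
#' centro-parietal topography, class-dependent lateralized band-limited
#' variance on the central channels (elevated contralaterally to the
#' attended hand), 1/f background noise, and optional frontal blink
#' artifacts. All numeric defaults are generator choices emulating the
#' structure of real recordings, not measured values.
#'
#' @param n_channels Channel count; the default 30 uses [montage_1020()].
#' @param fs Sampling rate in Hz.
#' @param p300_latency Peak latency of the planted P300 in ms after target
#'   onset.
#' @param p300_width Full width of the raised-cosine P300 bump in ms.
#' @param p300_amplitude Peak amplitude in microvolts at the topography
#'   maximum; applied to attended targets only.
#' @param p300_topography Per-channel gain vector (length `n_channels`);
#'   default is a centro-parietal map peaking at Cz/CP1/CP2/Pz.
#' @param lateral_band Frequency band (Hz) of the lateralized oscillatory
#'   sources.
#' @param lateral_power_ratio Variance ratio of the contralateral central
#'   source between its high (contralateral to the attended hand) and low
#'   state; 1 disables class-dependent structure.
#' @param lateral_scale Standard deviation (microvolts) of the lateral
#'   sources in their low state.
#' @param noise_exponent Spectral slope of the 1/f background noise.
#' @param noise_scale Per-channel noise standard deviation in microvolts.
#' @param blink_rate Blink artifacts per minute on the frontal channels
#'   (0 = off).
#' @param blink_amplitude Peak blink amplitude in microvolts at Fp1/Fp2.
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return A `generator_params` object (validated list).
#' @export
generator_params <- function(n_channels = 30, fs = 1000,
                             p300_latency = 350, p300_width = 300,
                             p300_amplitude = 5, p300_topography = NULL,
                             lateral_band = c(8, 20), lateral_power_ratio = 2,
                             lateral_scale = 4, noise_exponent = 1,
                             noise_scale = 5, blink_rate = 0,
                             blink_amplitude = 80, seed = 1) {
  if (fs <= 2 * max(lateral_band)) abort("`fs` must exceed twice the highest generated frequency")
  if (p300_amplitude < 0 || lateral_scale < 0 || noise_scale < 0 || blink_amplitude < 0) {
    abort("amplitudes must be >= 0")
  }
  if (lateral_power_ratio < 1) abort("`lateral_power_ratio` must be >= 1")
  if (!is.null(p300_topography) && length(p300_topography) != n_channels) {
    abort("`p300_topography` must have length `n_channels`")
  }
  structure(
    list(n_channels = n_channels, fs = fs, p300_latency = p300_latency,
         p300_width = p300_width, p300_amplitude = p300_amplitude,
         p300_topography = p300_topography, lateral_band = lateral_band,
         lateral_power_ratio = lateral_power_ratio,
         lateral_scale = lateral_scale, noise_exponent = noise_exponent,
         noise_scale = noise_scale, blink_rate = blink_rate,
         blink_amplitude = blink_amplitude, seed = as.integer(seed)),
    class = "generator_params"
  )
}

# named gain vector over a channel set, zero elsewhere
topo_vector <- function(channel_names, gains) {
  v <- numeric(length(channel_names))
  names(v) <- channel_names
  hit <- intersect(names(gains), channel_names)
  v[hit] <- unlist(gains)[hit]
  v
}

default_p300_topography <- function(channel_names) {
  topo_vector(channel_names, c(
    Cz = 1, CP1 = 0.85, CP2 = 0.85, Pz = 0.8, C3 = 0.5, C4 = 0.5,
    FC1 = 0.5, FC2 = 0.5, P3 = 0.45, P4 = 0.45, POz = 0.4, Fz = 0.35,
    F3 = 0.15, F4 = 0.15, CP5 = 0.2, CP6 = 0.2, O1 = 0.1, O2 = 0.1
  ))
}

lateral_topography <- function(channel_names, hemisphere = c("right", "left")) {
  hemisphere <- match.arg(hemisphere)
  if (hemisphere == "right") {
    topo_vector(channel_names, c(C4 = 1, FC2 = 0.35, CP2 = 0.35, FC6 = 0.25, CP6 = 0.25))
  } else {
    topo_vector(channel_names, c(C3 = 1, FC1 = 0.35, CP1 = 0.35, FC5 = 0.25, CP5 = 0.25))
  }
}

blink_topography <- function(channel_names) {
  topo_vector(channel_names, c(Fp1 = 1, Fp2 = 1, F3 = 0.45, F4 = 0.45,
                               F7 = 0.35, F8 = 0.35, Fz = 0.3, FC1 = 0.12, FC2 = 0.12))
}

#' Raised-cosine P300 template
#'
#' A smooth unimodal positive deflection: a Hann bump of the given full
#' `width`, peaking exactly at `latency` with peak value `amplitude` and
#' zero outside its support. The closed-form peak and width make planted
#' values recoverable in tests.
#'
#' @param latency Peak time in ms from epoch start.
#' @param width Full width (support) of the bump in ms.
#' @param amplitude Peak amplitude in microvolts.
#' @param fs Sampling rate in Hz.
#' @param length Template length in ms.
#' @return Numeric vector of `round(length * fs / 1000)` samples.
#' @examples
#' w <- make_p300_template(350, 300, 5, 1000, 1000)
#' which.max(w) - 1 # 350 (0-based peak sample)
#' @export
make_p300_template <- function(latency = 350, width = 300, amplitude = 5,
                               fs = 1000, length = 1000) {
  if (latency - width / 2 < 0 || latency + width / 2 > length) {
    abort("P300 support [latency - width/2, latency + width/2] must lie within the template length")
  }
  t_ms <- (seq_len(round(length * fs / 1000)) - 1) * 1000 / fs
  u <- (t_ms - latency) / width
  ifelse(abs(u) <= 0.5, amplitude * 0.5 * (1 + cos(2 * pi * u)), 0)
}

#' Multichannel 1/f ("pink") noise
#'
#' Spectrally shaped Gaussian noise: each channel's power spectral density
#' falls as `f^-exponent` (exponent 0 gives white noise). Channels are
#' independent, zero-mean, and scaled to the requested standard deviation.
#'
#' @param n_channels,n_samples Output dimensions.
#' @param exponent 1/f slope (PSD goes as `f^-exponent`).
#' @param scale Per-channel standard deviation; 0 returns a zero matrix.
#' @param seed Optional integer seed.
#' @return Numeric matrix, channels x samples.
#' @export
make_pink_noise <- function(n_channels, n_samples, exponent = 1, scale = 1,
                            seed = NULL) {
  if (n_samples <= 0) abort("`n_samples` must be > 0")
  gen <- function() {
    if (scale == 0) return(matrix(0, n_channels, n_samples))
    freqs <- seq_len(n_samples) - 1
    freqs <- pmin(freqs, n_samples - freqs) # two-sided bin distance from DC
    amp <- ifelse(freqs == 0, 0, freqs^(-exponent / 2))
    out <- matrix(0, n_channels, n_samples)
    for (ch in seq_len(n_channels)) {
      x <- rnorm(n_samples)
      shaped <- Re(fft(fft(x) * amp, inverse = TRUE)) / n_samples
      out[ch, ] <- scale * (shaped - mean(shaped)) / stats::sd(shaped)
    }
    out
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}

# band-limited unit-variance noise via FFT masking (exact band edges)
band_noise <- function(n_samples, fs, band) {
  x <- rnorm(n_samples)
  f <- (seq_len(n_samples) - 1) * fs / n_samples
  f <- pmin(f, fs - f)
  mask <- as.numeric(f >= band[1] & f <= band[2])
  y <- Re(fft(fft(x) * mask, inverse = TRUE)) / n_samples
  (y - mean(y)) / stats::sd(y)
}

#' Simulate a continuous EEG run for a stimulus schedule
#'
#' Builds a continuous recording realizing the forward model of
#' [generator_params()]: 1/f noise everywhere; a P300 template mixed
#' through the centro-parietal topography at every attended-target onset
#' (ignored targets and disturbances carry none); per block, two
#' band-limited oscillatory sources over the left and right central
#' channels whose variance ratio depends on the attended side (elevated
#' contralaterally); optional frontal blink bumps. Fully reproducible from
#' `params$seed`.
#'
#' @param schedule A [generate_schedule()] result.
#' @param params A [generator_params()].
#' @param pad_ms Silence appended after the last event (must cover the
#'   epoch window).
#' @return A list with `recording` (a [continuous_recording()] whose events
#'   are the schedule's stimuli, coded by condition label) and `truth`
#'   (planted topographies, latency, amplitudes and per-event labels).
#' @export
simulate_run <- function(schedule, params = generator_params(),
                         pad_ms = 1500) {
  stopifnot(inherits(schedule, "stimulus_schedule"),
            inherits(params, "generator_params"))
  ev <- schedule_to_events_table(schedule)
  if (nrow(ev) == 0) abort("`schedule` has no events")
  fs <- params$fs
  montage <- montage_1020()
  if (params$n_channels > nrow(montage)) {
    abort("`n_channels` exceeds the shipped 30-channel montage")
  }
  ch_names <- montage$name[seq_len(params$n_channels)]
  n_samples <- round((max(ev$onset_ms + ev$duration_ms) + pad_ms) * fs / 1000)

  topo_p300 <- params$p300_topography %||% default_p300_topography(ch_names)
  topo_right <- lateral_topography(ch_names, "right") # contralateral to left hand
  topo_left <- lateral_topography(ch_names, "left")

  withr::with_seed(params$seed, {
    x <- make_pink_noise(params$n_channels, n_samples,
                         params$noise_exponent, params$noise_scale)

    # P300 at attended-target onsets only
    template <- make_p300_template(params$p300_latency, params$p300_width,
                                   params$p300_amplitude, fs,
                                   params$p300_latency + params$p300_width / 2)
    att <- ev[ev$label %in% c("left_attended", "right_attended"), ]
    for (i in seq_len(nrow(att))) {
      s0 <- round(att$onset_ms[i] * fs / 1000) + 1
      idx <- s0:(s0 + length(template) - 1)
      idx <- idx[idx <= n_samples]
      x[, idx] <- x[, idx] + outer(topo_p300, template[seq_along(idx)])
    }

    # lateralized band-limited variance, constant within a block
    if (params$lateral_scale > 0) {
      blocks <- unique(ev$block)
      for (b in blocks) {
        evb <- ev[ev$block == b, ]
        s0 <- round(min(evb$onset_ms) * fs / 1000) + 1
        s1 <- min(n_samples, round((max(evb$onset_ms + evb$duration_ms) + pad_ms) * fs / 1000))
        n <- s1 - s0 + 1
        hi <- params$lateral_scale * sqrt(params$lateral_power_ratio)
        lo <- params$lateral_scale
        left_attended <- schedule$attended_side[b] == "left"
        sd_right <- if (left_attended) hi else lo # C4 source
        sd_left <- if (left_attended) lo else hi # C3 source
        x[, s0:s1] <- x[, s0:s1] +
          outer(topo_right, sd_right * band_noise(n, fs, params$lateral_band)) +
          outer(topo_left, sd_left * band_noise(n, fs, params$lateral_band))
      }
    }

    # frontal blink bumps
    blink_onsets <- integer(0)
    if (params$blink_rate > 0) {
      minutes <- n_samples / fs / 60
      n_blinks <- rpois(1, params$blink_rate * minutes)
      blink <- make_p300_template(200, 350, 1, fs, 400)
      topo_b <- blink_topography(ch_names)
      if (n_blinks > 0) {
        blink_onsets <- sort(sample.int(n_samples - length(blink), n_blinks))
        amps <- params$blink_amplitude * exp(rnorm(n_blinks, 0, 0.2))
        for (i in seq_len(n_blinks)) {
          idx <- blink_onsets[i]:(blink_onsets[i] + length(blink) - 1)
          x[, idx] <- x[, idx] + outer(topo_b, amps[i] * blink)
        }
      }
    }

    recording <- continuous_recording(
      x, fs, ch_names,
      channel_positions = montage[seq_len(params$n_channels), ],
      events = tibble(onset_sample = round(ev$onset_ms * fs / 1000),
                      code = ev$label),
      reference_label = "simulated common reference"
    )
    truth <- list(
      event_labels = ev$label, p300_topography = topo_p300,
      lateral_topography_right = topo_right,
      lateral_topography_left = topo_left,
      p300_latency = params$p300_latency,
      p300_amplitude = params$p300_amplitude,
      blink_onset_samples = blink_onsets, params = params
    )
    list(recording = recording, truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
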