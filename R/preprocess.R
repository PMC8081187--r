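# Butterworth band-pass as a cascade of a high-pass and a low-pass section.
# A direct transfer-function band-pass of order 4 is numerically unstable at
# the narrow normalized bands this pipeline uses (e.g. 0.5-3 Hz at 1 kHz);
# the cascaded sections are stable and keep the passband flat within 1%.
design_bandpass <- function(low, high, fs, order = 4) {
  if (!(low > 0 && low < high && high < fs / 2)) {
    abort(paste0("band edges must satisfy 0 < low < high < fs/2 (got ",
                 low, "-", high, " Hz at fs=", fs, ")"))
  }
  list(hp = signal::butter(order, low / (fs / 2), type = "high"),
       lp = signal::butter(order, high / (fs / 2), type = "low"))
}

apply_bandpass_vec <- function(x, flt, mode) {
  x <- x - mean(x) # the high-pass removes DC anyway; this shrinks edge transients
  if (mode == "zero-phase") {
    signal::filtfilt(flt$lp, signal::filtfilt(flt$hp, x))
  } else {
    signal::filter(flt$lp, signal::filter(flt$hp, x))
  }
}

#' Band-pass filter a recording or epoch set
#'
#' Fourth-order Butterworth band-pass applied per channel. Zero-phase mode
#' (the default, for offline analysis) runs the filter forward and backward,
#' doubling the effective order and cancelling group delay so ERP peak
#' latencies are not shifted; causal mode runs a single forward pass, for
#' realistic sliding-window evaluation.
#'
#' @param x A [continuous_recording()] or [epoch_set()].
#' @param low,high Band edges in Hz (0 < low < high < fs/2).
#' @param order Butterworth order of each section.
#' @param mode `"zero-phase"` or `"causal"`.
#' @return Object of the same class with filtered data.
#' @export
bandpass <- function(x, low = 0.5, high = 30, order = 4,
                     mode = c("zero-phase", "causal")) {
  mode <- match.arg(mode)
  flt <- design_bandpass(low, high, x$fs, order)
  if (inherits(x, "continuous_recording")) {
    for (ch in seq_len(nrow(x$data))) {
      x$data[ch, ] <- apply_bandpass_vec(x$data[ch, ], flt, mode)
    }
  } else if (inherits(x, "epoch_set")) {
    d <- dim(x$data)
    for (ep in seq_len(d[1])) {
      for (ch in seq_len(d[2])) {
        x$data[ep, ch, ] <- apply_bandpass_vec(x$data[ep, ch, ], flt, mode)
      }
    }
  } else {
    abort("`x` must be a continuous_recording or epoch_set")
  }
  x
}

#' Re-reference to the mean of reference channels
#'
#' Subtracts the average of the reference channels (the mastoids TP9/TP10
#' by default) from every channel. Applying it twice is a no-op, since the
#' referenced channels' mean becomes zero after the first pass.
#'
#' @param recording A [continuous_recording()].
#' @param ref_channels Channel names to average as the reference.
#' @return The re-referenced recording, with `reference_label` updated.
#' @export
rereference <- function(recording, ref_channels = c("TP9", "TP10")) {
  stopifnot(inherits(recording, "continuous_recording"))
  idx <- match(ref_channels, recording$channel_names)
  if (anyNA(idx)) {
    abort(paste0("reference channel(s) not found: ",
                 paste(ref_channels[is.na(idx)], collapse = ", ")))
  }
  ref <- colMeans(recording$data[idx, , drop = FALSE])
  recording$data <- sweep(recording$data, 2, ref)
  recording$reference_label <- paste0("avg(", paste(ref_channels, collapse = ","), ")")
  recording
}

#' Drop channels from a recording
#'
#' Utility for excluding non-EEG channels (the recording montage carries an
#' ECG electrode that takes no part in the analysis).
#'
#' @param recording A [continuous_recording()].
#' @param channels Names to drop; names not present are ignored.
#' @return The reduced recording.
#' @export
drop_channels <- function(recording, channels = "ECG") {
  stopifnot(inherits(recording, "continuous_recording"))
  keep <- !(recording$channel_names %in% channels)
  recording$data <- recording$data[keep, , drop = FALSE]
  recording$channel_names <- recording$channel_names[keep]
  if (!is.null(recording$channel_positions)) {
    recording$channel_positions <-
      recording$channel_positions[recording$channel_positions$name %in%
                                    recording$channel_names, ]
  }
  recording
}

#' Cut stimulus-locked epochs with baseline correction
#'
#' Extracts a `tmin..tmax` ms window (inclusive at both ends at sample
#' resolution; 1201 samples for -200..1000 ms at 1,000 Hz) around each
#' event onset and subtracts the per-epoch, per-channel mean of the
#' baseline window. Events whose window would exceed the recording bounds
#' are dropped with a warning stating the exact count.
#'
#' @param recording A [continuous_recording()].
#' @param events Events tibble with `onset_ms` and a `label` column (see
#'   [schedule_to_events_table()]); if `NULL`, the recording's own event
#'   markers are used (codes become labels).
#' @param tmin,tmax Window bounds in ms relative to onset.
#' @param baseline Baseline window in ms within `[tmin, 0]`, or `NULL` to
#'   skip baseline correction.
#' @return An [epoch_set()]; epoch ids are the event onsets in ms.
#' @export
epoch_recording <- function(recording, events = NULL, tmin = -200,
                            tmax = 1000, baseline = c(-200, 0)) {
  stopifnot(inherits(recording, "continuous_recording"))
  fs <- recording$fs
  if (is.null(events)) {
    onset_samples <- recording$events$onset_sample
    labels <- recording$events$code
    onset_ms <- onset_samples * 1000 / fs
  } else {
    onset_ms <- events$onset_ms
    onset_samples <- round(onset_ms * fs / 1000)
    labels <- if ("label" %in% names(events)) events$label else events$kind
  }
  if (length(onset_samples) == 0) abort("no events to epoch")

  pre <- round(tmin * fs / 1000)
  post <- round(tmax * fs / 1000)
  n_smp <- post - pre + 1
  first <- onset_samples + pre # 0-based
  last <- onset_samples + post
  ok <- first >= 0 & last < ncol(recording$data)
  if (any(!ok)) {
    warn(paste0("dropped ", sum(!ok), " of ", length(ok),
                " epochs whose window exceeds the recording bounds"))
  }
  if (!any(ok)) abort("no epoch fits within the recording bounds")
  keep <- which(ok)
  n_ch <- nrow(recording$data)
  out <- array(0, dim = c(length(keep), n_ch, n_smp))
  for (i in seq_along(keep)) {
    idx <- (first[keep[i]]:last[keep[i]]) + 1
    out[i, , ] <- recording$data[, idx]
  }
  eps <- epoch_set(out, fs, pre * 1000 / fs, post * 1000 / fs,
                   labels[keep], recording$channel_names,
                   baseline = baseline, ids = round(onset_ms[keep]))
  if (!is.null(baseline)) baseline_correct(eps) else eps
}

# subtract the per-epoch, per-channel mean over the baseline window
baseline_correct <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  bl <- epochs$baseline
  if (is.null(bl)) return(epochs)
  times <- epoch_times(epochs)
  idx <- which(times >= bl[1] - 1e-9 & times <= bl[2] + 1e-9)
  means <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(means) # recycles over the 3rd dim
  epochs
}
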