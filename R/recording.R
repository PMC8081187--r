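#' Continuous multichannel recording
#'
#' Light container for continuous EEG: a channels x samples matrix in
#' microvolts plus sampling rate, channel names, optional 2-D montage
#' coordinates and an event list. Sample indexing is 0-based (an event at
#' `onset_sample = 0` starts at the first stored sample) and event spans are
#' half-open `[onset, onset + duration)`.
#'
#' @param data Numeric matrix, channels x samples, microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one name per row of `data`.
#' @param channel_positions Optional tibble with columns `name`, `x`, `y`.
#' @param events Tibble with columns `onset_sample` (0-based) and `code`.
#' @param reference_label Free-text description of the reference.
#' @return A `continuous_recording` object.
#' @export
continuous_recording <- function(data, fs, channel_names,
                                 channel_positions = NULL,
                                 events = empty_marker_table(),
                                 reference_label = "as-recorded") {
  if (!is.matrix(data) || !is.numeric(data)) abort("`data` must be a numeric matrix")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) abort("`fs` must be a positive scalar")
  if (length(channel_names) != nrow(data)) {
    abort("`channel_names` length must equal the channel (row) count of `data`")
  }
  events <- as_tibble(events)
  if (!all(c("onset_sample", "code") %in% names(events))) {
    abort("`events` needs columns `onset_sample` and `code`")
  }
  if (nrow(events) > 0 &&
      (any(events$onset_sample < 0) || any(events$onset_sample >= ncol(data)))) {
    abort("event onsets must lie within [0, n_samples)")
  }
  rownames(data) <- channel_names
  structure(
    list(data = data, fs = fs, channel_names = as.character(channel_names),
         channel_positions = channel_positions, events = events,
         reference_label = reference_label),
    class = "continuous_recording"
  )
}

empty_marker_table <- function() {
  tibble(onset_sample = integer(), code = character())
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat("<continuous_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", round(ncol(x$data) / x$fs, 1), " s), ",
      nrow(x$events), " events, reference: ", x$reference_label, "\n", sep = "")
  invisible(x)
}

#' Set of stimulus-locked epochs
#'
#' Trials x channels x samples array cut around stimulus onsets. The time
#' axis runs from `tmin` to `tmax` ms relative to onset, inclusive at both
#' ends at sample resolution, so a -200..1000 ms window at 1,000 Hz holds
#' 1201 samples and time 0 is the onset sample.
#'
#' @param data Numeric 3-D array, epochs x channels x samples.
#' @param fs Sampling rate in Hz.
#' @param tmin,tmax Epoch window bounds in ms relative to stimulus onset.
#' @param labels Per-epoch condition label (`left_attended`,
#'   `right_attended`, `ignored` or `disturbance`).
#' @param channel_names One name per channel.
#' @param baseline Baseline window in ms (within `[tmin, 0]`) that was, or
#'   is to be, subtracted; `NULL` if none.
#' @param ids Stable per-epoch identifiers (used for reproducible fold
#'   assignment); default onset order.
#' @return An `epoch_set` object.
#' @export
epoch_set <- function(data, fs, tmin, tmax, labels, channel_names,
                      baseline = NULL, ids = NULL) {
  if (!is.array(data) || length(dim(data)) != 3) {
    abort("`data` must be a 3-D array (epochs x channels x samples)")
  }
  expected <- round((tmax - tmin) * fs / 1000) + 1
  if (dim(data)[3] != expected) {
    abort(paste0("sample count ", dim(data)[3], " does not match window ",
                 tmin, "..", tmax, " ms at ", fs, " Hz (expected ", expected, ")"))
  }
  if (length(labels) != dim(data)[1]) abort("one label per epoch required")
  if (length(channel_names) != dim(data)[2]) abort("one name per channel required")
  if (!is.null(baseline) &&
      (baseline[1] < tmin || baseline[2] > 0 || baseline[1] > baseline[2])) {
    abort("`baseline` must lie within [tmin, 0]")
  }
  if (is.null(ids)) ids <- seq_len(dim(data)[1])
  structure(
    list(data = data, fs = fs, tmin = tmin, tmax = tmax,
         labels = as.character(labels),
         channel_names = as.character(channel_names),
         baseline = baseline, ids = ids),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> ", dim(x$data)[1], " epochs x ", dim(x$data)[2],
      " channels x ", dim(x$data)[3], " samples (", x$tmin, "..", x$tmax,
      " ms @ ", x$fs, " Hz)\n", sep = "")
  tab <- table(x$labels)
  cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Time axis of an epoch set
#' @param epochs An [epoch_set()].
#' @return Numeric vector of times in ms relative to stimulus onset.
#' @export
epoch_times <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  seq(epochs$tmin, epochs$tmax, by = 1000 / epochs$fs)
}

#' Subset an epoch set
#'
#' @param epochs An [epoch_set()].
#' @param labels Keep epochs whose label is in this set (default: all).
#' @param idx Optional explicit epoch indices (applied after `labels`).
#' @param channels Optional channel-name subset.
#' @param window Optional time window in ms `c(from, to)` to crop to
#'   (inclusive at sample resolution).
#' @return A new `epoch_set`.
#' @export
filter_epochs <- function(epochs, labels = NULL, idx = NULL, channels = NULL,
                          window = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- seq_len(dim(epochs$data)[1])
  if (!is.null(labels)) keep <- keep[epochs$labels[keep] %in% labels]
  if (!is.null(idx)) keep <- keep[idx]
  ch <- seq_len(dim(epochs$data)[2])
  if (!is.null(channels)) {
    ch <- match(channels, epochs$channel_names)
    if (anyNA(ch)) abort(paste0("unknown channel(s): ",
                                paste(channels[is.na(ch)], collapse = ", ")))
  }
  tmin <- epochs$tmin; tmax <- epochs$tmax
  smp <- seq_len(dim(epochs$data)[3])
  if (!is.null(window)) {
    if (window[1] < tmin || window[2] > tmax || window[1] >= window[2]) {
      abort("`window` must lie within the epoch bounds")
    }
    times <- epoch_times(epochs)
    smp <- which(times >= window[1] - 1e-9 & times <= window[2] + 1e-9)
    tmin <- times[smp[1]]; tmax <- times[smp[length(smp)]]
  }
  epoch_set(epochs$data[keep, ch, smp, drop = FALSE], epochs$fs, tmin, tmax,
            epochs$labels[keep], epochs$channel_names[ch],
            baseline = if (is.null(window)) epochs$baseline else NULL,
            ids = epochs$ids[keep])
}
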