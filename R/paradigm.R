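#' Oddball paradigm configuration
#'
#' Describes the timing of the two-class tactile oddball protocol: rare
#' 100 Hz / 150 ms target stimuli embedded among frequent 23 Hz / 200 ms
#' disturbance stimuli with a 400 ms inter-stimulus interval, six stimuli
#' per trial, 13 trials per block and eight blocks per run, with only one
#' target site (left or right index finger) stimulated within a block.
#'
#' The stimulus drive frequencies are carried as metadata only; event timing
#' is what matters downstream, so no carrier waveform is synthesized.
#'
#' @param target_freq Target stimulus drive frequency in Hz.
#' @param target_dur Target stimulus duration in ms.
#' @param disturb_freq Disturbance stimulus drive frequency in Hz.
#' @param disturb_dur Disturbance stimulus duration in ms.
#' @param isi Inter-stimulus interval (gap between consecutive stimuli
#'   within a trial) in ms.
#' @param stimuli_per_trial Stimuli per trial (one of which is the target,
#'   except in the block-marker trial).
#' @param trials_per_block Trials per block; the first trial of every block
#'   is all disturbances and marks the block start.
#' @param blocks_per_run Blocks per run; the attended/stimulated side is
#'   constant within a block.
#' @param inter_block_break Break between blocks, in seconds.
#' @param inter_trial_gap Extra gap between consecutive trials, in ms.
#' @param sides The two stimulation sites.
#' @return A `paradigm_config` object (a validated list).
#' @examples
#' cfg <- paradigm_config()
#' trial_duration(cfg)
#' @export
paradigm_config <- function(target_freq = 100, target_dur = 150,
                            disturb_freq = 23, disturb_dur = 200,
                            isi = 400, stimuli_per_trial = 6,
                            trials_per_block = 13, blocks_per_run = 8,
                            inter_block_break = 60, inter_trial_gap = 0,
                            sides = c("left", "right")) {
  cfg <- list(
    target_freq = target_freq, target_dur = target_dur,
    disturb_freq = disturb_freq, disturb_dur = disturb_dur,
    isi = isi, stimuli_per_trial = stimuli_per_trial,
    trials_per_block = trials_per_block, blocks_per_run = blocks_per_run,
    inter_block_break = inter_block_break, inter_trial_gap = inter_trial_gap,
    sides = sides
  )
  class(cfg) <- "paradigm_config"
  validate_paradigm_config(cfg)
}

validate_paradigm_config <- function(cfg) {
  chk <- function(ok, field, what) {
    if (!ok) abort(paste0("invalid paradigm configuration: `", field, "` ", what),
                   class = "tactileP300_config_error")
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  chk(num1(cfg$target_dur) && cfg$target_dur > 0, "target_dur", "must be > 0")
  chk(num1(cfg$disturb_dur) && cfg$disturb_dur >= 0, "disturb_dur", "must be >= 0")
  chk(num1(cfg$isi) && cfg$isi >= 0, "isi", "must be >= 0")
  chk(num1(cfg$stimuli_per_trial) && cfg$stimuli_per_trial >= 1,
      "stimuli_per_trial", "must be >= 1")
  chk(num1(cfg$trials_per_block) && cfg$trials_per_block >= 1,
      "trials_per_block", "must be >= 1")
  chk(num1(cfg$blocks_per_run) && cfg$blocks_per_run >= 1,
      "blocks_per_run", "must be >= 1")
  chk(num1(cfg$inter_block_break) && cfg$inter_block_break >= 0,
      "inter_block_break", "must be >= 0")
  chk(num1(cfg$inter_trial_gap) && cfg$inter_trial_gap >= 0,
      "inter_trial_gap", "must be >= 0")
  chk(is.character(cfg$sides) && length(cfg$sides) == 2, "sides",
      "must name exactly two sites")
  cfg
}

#' Duration of one target trial
#'
#' A target trial holds one target stimulus and `stimuli_per_trial - 1`
#' disturbances, separated by the inter-stimulus interval:
#' `target_dur + (n - 1) * disturb_dur + (n - 1) * isi`. Only the
#' between-stimulus gaps count, which reproduces the protocol's 3.15 s
#' trial at the defaults (150 + 5 * 200 + 5 * 400 ms).
#'
#' @param config A [paradigm_config()].
#' @return Trial duration in ms.
#' @examples
#' trial_duration(paradigm_config()) # 3150
#' @export
trial_duration <- function(config) {
  stopifnot(inherits(config, "paradigm_config"))
  n <- config$stimuli_per_trial
  config$target_dur + (n - 1) * config$disturb_dur + (n - 1) * config$isi
}

# duration of the all-disturbance marker trial
marker_trial_duration <- function(config) {
  n <- config$stimuli_per_trial
  n * config$disturb_dur + (n - 1) * config$isi
}

#' Generate the stimulus schedule of one run
#'
#' Lays out `blocks_per_run` blocks of `trials_per_block` trials. The first
#' trial of each block is all disturbances (the block-start marker); every
#' later trial carries exactly one target at a position drawn uniformly at
#' random among the `stimuli_per_trial` slots. All stimuli of a block are
#' delivered to that block's single site; by default sides alternate
#' left, right, left, ... across blocks.
#'
#' The same `seed` always yields an identical schedule. Onsets are integer
#' milliseconds so that at a 1,000 Hz sampling rate events align exactly to
#' samples.
#'
#' @param config A [paradigm_config()].
#' @param seed Integer seed for the pseudorandom target placement.
#' @param sides_order Optional explicit character vector of stimulated sides,
#'   one per block (recycled if shorter).
#' @param attend_sides Optional attended side per block. Defaults to the
#'   stimulated side (the subject attends the stimulated hand); set it to a
#'   different sequence to label targets on unattended sites as ignored.
#' @return A `stimulus_schedule`: a list with `events` (a tibble with one
#'   row per stimulus: `onset_ms`, `duration_ms`, `kind`, `site`, `block`,
#'   `trial`, `slot`), `attended_side` (per block), `config` and `seed`.
#' @examples
#' sched <- generate_schedule(paradigm_config(), seed = 1)
#' nrow(sched$events) # 624
#' sum(sched$events$kind == "target") # 96
#' @export
generate_schedule <- function(config, seed, sides_order = NULL,
                              attend_sides = NULL) {
  stopifnot(inherits(config, "paradigm_config"))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("`seed` must be a single integer (reproducibility contract)")
  }
  n_blk <- config$blocks_per_run
  n_tri <- config$trials_per_block
  n_sti <- config$stimuli_per_trial
  if (is.null(sides_order)) {
    sides_order <- rep(config$sides, length.out = n_blk)
  } else {
    sides_order <- rep(sides_order, length.out = n_blk)
  }
  if (!all(sides_order %in% config$sides)) {
    abort("`sides_order` contains sites not in `config$sides`")
  }
  if (is.null(attend_sides)) attend_sides <- sides_order
  attend_sides <- rep(attend_sides, length.out = n_blk)

  target_slots <- withr::with_seed(as.integer(seed), {
    matrix(sample.int(n_sti, n_blk * max(n_tri - 1, 0), replace = TRUE),
           nrow = n_blk)
  })

  rows <- vector("list", n_blk * n_tri)
  cursor <- 0
  k <- 0L
  for (b in seq_len(n_blk)) {
    for (tr in seq_len(n_tri)) {
      kinds <- rep("disturbance", n_sti)
      if (tr > 1) kinds[target_slots[b, tr - 1]] <- "target"
      durs <- ifelse(kinds == "target", config$target_dur, config$disturb_dur)
      onsets <- cursor + cumsum(c(0, head(durs, -1) + config$isi))
      k <- k + 1L
      rows[[k]] <- tibble(
        onset_ms = round(onsets), duration_ms = durs, kind = kinds,
        site = sides_order[b], block = b, trial = tr, slot = seq_len(n_sti)
      )
      cursor <- onsets[n_sti] + durs[n_sti] + config$inter_trial_gap
    }
    cursor <- cursor + config$inter_block_break * 1000
  }
  events <- dplyr::bind_rows(rows)
  structure(
    list(events = events, attended_side = attend_sides,
         stimulated_side = sides_order, config = config,
         seed = as.integer(seed)),
    class = "stimulus_schedule"
  )
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat("<stimulus_schedule> ", x$config$blocks_per_run, " blocks x ",
      x$config$trials_per_block, " trials x ", x$config$stimuli_per_trial,
      " stimuli = ", nrow(x$events), " events (",
      sum(x$events$kind == "target"), " targets), seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

#' Flatten a schedule to an events table
#'
#' One row per stimulus event, sorted by onset, with the condition label
#' attached: targets on the block's attended side are `left_attended` /
#' `right_attended`, targets elsewhere `ignored`, and all remaining stimuli
#' `disturbance`.
#'
#' @param schedule A [generate_schedule()] result.
#' @return A tibble with columns `onset_ms`, `duration_ms`, `kind`, `site`,
#'   `block`, `trial` and `label`.
#' @export
schedule_to_events_table <- function(schedule) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  ev <- schedule$events
  if (nrow(ev) == 0) {
    return(tibble(onset_ms = numeric(), duration_ms = numeric(),
                  kind = character(), site = character(), block = integer(),
                  trial = integer(), label = character()))
  }
  ev <- ev[order(ev$onset_ms), ]
  attended <- schedule$attended_side[ev$block]
  label <- ifelse(ev$kind == "disturbance", "disturbance",
                  ifelse(ev$site == attended, paste0(ev$site, "_attended"),
                         "ignored"))
  out <- dplyr::mutate(ev, label = label)
  dplyr::select(out, "onset_ms", "duration_ms", "kind", "site", "block",
                "trial", "label")
}
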