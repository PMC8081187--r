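#' Write / read a tab-separated events table
#'
#' The events table is the plain-text interface between the paradigm and
#' the EEG pipeline: one row per stimulus with onsets in milliseconds
#' (BIDS-events-like). Writing then reading reproduces the table exactly.
#'
#' @param events Tibble as produced by [schedule_to_events_table()]; any
#'   extra columns are preserved.
#' @param path Output file path.
#' @return `write_events_table()` returns `path` invisibly;
#'   `read_events_table()` returns the tibble.
#' @export
write_events_table <- function(events, path) {
  stopifnot(is.data.frame(events))
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_table
#' @export
read_events_table <- function(path) {
  if (!file.exists(path)) abort(paste0("events file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) abort("events file is empty (no header)")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  required <- c("onset_ms", "duration_ms", "kind", "site", "block", "trial")
  if (!all(required %in% header)) {
    abort(paste0("events file lacks required column(s): ",
                 paste(setdiff(required, header), collapse = ", ")))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  rows <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(rows) != length(header))
  if (length(bad) > 0) {
    abort(paste0("malformed events row at line ", bad[1] + 1, ": expected ",
                 length(header), " tab-separated fields, got ",
                 lengths(rows)[bad[1]]))
  }
  tbl <- as_tibble(as.data.frame(do.call(rbind, rows),
                                 stringsAsFactors = FALSE))
  if (length(body) == 0) {
    tbl <- as_tibble(stats::setNames(
      replicate(length(header), character(0), simplify = FALSE), header))
  } else {
    names(tbl) <- header
  }
  for (col in c("onset_ms", "duration_ms", "block", "trial")) {
    v <- suppressWarnings(as.numeric(tbl[[col]]))
    if (anyNA(v) && nrow(tbl) > 0) {
      abort(paste0("malformed events row at line ",
                   which(is.na(v))[1] + 1, ": `", col, "` is not numeric"))
    }
    tbl[[col]] <- v
  }
  tbl
}

#' Attach an events table to a recording
#'
#' Converts onsets from milliseconds to 0-based sample indices at the
#' recording's sampling rate (`round(onset_ms * fs / 1000)`) and stores
#' them as the recording's events, coded by `label` when present
#' (otherwise by `kind`).
#'
#' @param recording A [continuous_recording()].
#' @param events Events tibble with `onset_ms` and `kind` (and optionally
#'   `label`) columns.
#' @return The recording with events replaced.
#' @export
attach_events <- function(recording, events) {
  stopifnot(inherits(recording, "continuous_recording"))
  code <- if ("label" %in% names(events)) events$label else events$kind
  recording$events <- tibble(
    onset_sample = as.integer(round(events$onset_ms * recording$fs / 1000)),
    code = as.character(code)
  )
  recording
}
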