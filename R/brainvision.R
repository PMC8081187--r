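#' Write a recording as a BrainVision file triplet
#'
#' Emits the `.vhdr` header, `.vmrk` marker file and `.eeg` binary payload.
#' Only the dialect this pipeline needs is produced: MULTIPLEXED channel
#' orientation with `IEEE_FLOAT_32` or `INT_16` binary data and marker file
#' format 1. The header records the sampling rate as a sampling interval in
#' microseconds. For `INT_16`, samples are stored as
#' `round(value / resolution)` so the round-trip error is at most half a
#' resolution step; `IEEE_FLOAT_32` stores single-precision values directly
#' (exact for values representable in single precision).
#'
#' @param recording A [continuous_recording()].
#' @param basepath Output path without extension; the three files are
#'   `basepath.vhdr`, `basepath.vmrk`, `basepath.eeg`.
#' @param binary_format `"IEEE_FLOAT_32"` (default) or `"INT_16"`.
#' @param resolution Per-sample resolution in microvolts for the `INT_16`
#'   path (ignored for floats, where it is 1).
#' @return Invisibly, the header path.
#' @export
write_brainvision <- function(recording, basepath,
                              binary_format = c("IEEE_FLOAT_32", "INT_16"),
                              resolution = 0.1) {
  stopifnot(inherits(recording, "continuous_recording"))
  binary_format <- match.arg(binary_format)
  base <- basename(basepath)
  dir <- dirname(basepath)
  if (!dir.exists(dir)) abort(paste0("cannot write to '", dir, "': no such directory"))
  n_ch <- nrow(recording$data)
  res <- if (binary_format == "INT_16") resolution else 1

  hdr <- c(
    "BrainVision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_ch),
    paste0("SamplingInterval=", format(1e6 / recording$fs, scientific = FALSE)),
    "",
    "[Binary Infos]",
    paste0("BinaryFormat=", binary_format),
    "",
    "[Channel Infos]",
    paste0("Ch", seq_len(n_ch), "=", recording$channel_names, ",,",
           format(res, scientific = FALSE), ",µV")
  )
  writeLines(hdr, paste0(basepath, ".vhdr"), useBytes = FALSE)

  mk <- c(
    "BrainVision Data Exchange Marker File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000"
  )
  if (nrow(recording$events) > 0) {
    mk <- c(mk, paste0(
      "Mk", seq_len(nrow(recording$events)) + 1, "=Stimulus,",
      recording$events$code, ",", recording$events$onset_sample + 1, ",1,0"
    ))
  }
  writeLines(mk, paste0(basepath, ".vmrk"))

  con <- file(paste0(basepath, ".eeg"), "wb")
  on.exit(close(con))
  # MULTIPLEXED: all channels of sample 1, then sample 2, ... (column-major
  # order of the channels x samples matrix)
  if (binary_format == "IEEE_FLOAT_32") {
    writeBin(as.numeric(recording$data), con, size = 4, endian = "little")
  } else {
    ints <- as.integer(pmax(-32768, pmin(32767, round(recording$data / res))))
    writeBin(ints, con, size = 2, endian = "little")
  }
  invisible(paste0(basepath, ".vhdr"))
}

parse_vhdr_sections <- function(lines) {
  sections <- list()
  current <- NULL
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    if (grepl("^\\s*\\[.+\\]\\s*$", ln)) {
      current <- gsub("^\\s*\\[|\\]\\s*$", "", ln)
      sections[[current]] <- character(0)
    } else if (!is.null(current) && grepl("=", ln, fixed = TRUE)) {
      sections[[current]] <- c(sections[[current]], trimws(ln))
    }
  }
  lapply(sections, function(kv) {
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    stats::setNames(vals, keys)
  })
}

#' Read a BrainVision recording
#'
#' Parses the `.vhdr` header, loads the `.eeg` binary payload and the
#' `.vmrk` markers, and returns a [continuous_recording()] scaled to
#' microvolts via each channel's resolution. Supports the MULTIPLEXED
#' orientation with `IEEE_FLOAT_32` and `INT_16` binary formats; any other
#' dialect (e.g. VECTORIZED orientation) is rejected with an explicit
#' error rather than read incorrectly. Marker positions (1-based in the
#' format) are converted to 0-based sample indices.
#'
#' @param header_path Path to the `.vhdr` file.
#' @return A [continuous_recording()].
#' @export
read_brainvision <- function(header_path) {
  if (!file.exists(header_path)) {
    abort(paste0("header file not found: ", header_path))
  }
  lines <- readLines(header_path, encoding = "UTF-8", warn = FALSE)
  sec <- parse_vhdr_sections(lines)
  common <- sec[["Common Infos"]]
  binfo <- sec[["Binary Infos"]]
  chinfo <- sec[["Channel Infos"]]
  if (is.null(common)) abort("malformed header: no [Common Infos] section")

  orientation <- common[["DataOrientation"]] %||% "MULTIPLEXED"
  if (!identical(orientation, "MULTIPLEXED")) {
    abort(paste0("unsupported DataOrientation '", orientation,
                 "': only MULTIPLEXED is implemented"))
  }
  fmt <- binfo[["BinaryFormat"]] %||% "IEEE_FLOAT_32"
  if (!fmt %in% c("IEEE_FLOAT_32", "INT_16")) {
    abort(paste0("unsupported BinaryFormat '", fmt,
                 "': only IEEE_FLOAT_32 and INT_16 are implemented"))
  }
  n_ch <- as.integer(common[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(common[["SamplingInterval"]])

  ch_fields <- strsplit(unname(chinfo), ",", fixed = TRUE)
  ch_names <- vapply(ch_fields, `[`, "", 1)
  ch_res <- vapply(ch_fields, function(f) {
    r <- suppressWarnings(as.numeric(f[3]))
    if (is.na(r)) 1 else r
  }, 0)
  if (length(ch_names) != n_ch) {
    abort("header inconsistent: channel list length differs from NumberOfChannels")
  }

  dir <- dirname(header_path)
  eeg_path <- file.path(dir, common[["DataFile"]])
  vmrk_path <- file.path(dir, common[["MarkerFile"]])
  if (!file.exists(eeg_path)) abort(paste0("missing data file: ", eeg_path))

  bytes <- if (fmt == "IEEE_FLOAT_32") 4L else 2L
  size <- file.info(eeg_path)$size
  if (size %% (n_ch * bytes) != 0) {
    abort(paste0("truncated or corrupt data file: ", size,
                 " bytes is not a whole number of ", n_ch, "-channel frames"))
  }
  n_samples <- size %/% (n_ch * bytes)
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  raw_vals <- if (fmt == "IEEE_FLOAT_32") {
    readBin(con, "numeric", n = n_ch * n_samples, size = 4, endian = "little")
  } else {
    readBin(con, "integer", n = n_ch * n_samples, size = 2, signed = TRUE,
            endian = "little")
  }
  data <- matrix(raw_vals, nrow = n_ch) * ch_res

  events <- empty_marker_table()
  if (file.exists(vmrk_path)) {
    mk <- parse_vhdr_sections(readLines(vmrk_path, encoding = "UTF-8",
                                        warn = FALSE))[["Marker Infos"]]
    if (length(mk)) {
      fields <- strsplit(unname(mk), ",", fixed = TRUE)
      types <- vapply(fields, `[`, "", 1)
      keep <- types != "New Segment"
      if (any(keep)) {
        events <- tibble(
          onset_sample = vapply(fields[keep],
                                function(f) as.integer(f[3]) - 1L, 1L),
          code = vapply(fields[keep], `[`, "", 2)
        )
      }
    }
  } else if (!is.null(common[["MarkerFile"]])) {
    abort(paste0("missing marker file: ", vmrk_path))
  }

  pos <- tryCatch(montage_1020(ch_names), error = function(e) NULL)
  continuous_recording(data, fs, ch_names, channel_positions = pos,
                       events = events, reference_label = "as-recorded")
}
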