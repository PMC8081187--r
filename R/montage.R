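#' Standard 10-20 montage used by the simulator
#'
#' Thirty EEG channels of the extended international 10-20 system with
#' schematic two-dimensional scalp coordinates (top view, nose up, unit
#' radius at the ear line). This is the montage the synthetic-data generator
#' emulates: a 32-conductor cap with the ECG channel excluded and TP9/TP10
#' available as mastoid references.
#'
#' @param channels Optional character vector to subset (and order) the
#'   montage by channel name.
#' @return A tibble with columns `name`, `x`, `y`.
#' @examples
#' montage_1020()
#' montage_1020(c("Cz", "C3", "C4"))
#' @export
montage_1020 <- function(channels = NULL) {
  path <- system.file("extdata", "montage_1020.tsv", package = "tactileP300")
  tbl <- as_tibble(read.delim(path, stringsAsFactors = FALSE))
  if (!is.null(channels)) {
    missing <- setdiff(channels, tbl$name)
    if (length(missing) > 0) {
      abort(paste0("unknown channel(s): ", paste(missing, collapse = ", ")))
    }
    tbl <- tbl[match(channels, tbl$name), ]
  }
  tbl
}
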