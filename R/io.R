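#' Write a voltage series as raw binary with a JSON sidecar
#'
#' Little-endian 64-bit floats plus `<path>.json` recording the sampling
#' rate, units, length and channel index.
#'
#' @param x numeric signal (V)
#' @param path output file path (binary); the sidecar is `<path>.json`
#' @param fs sampling rate (Hz)
#' @param channel channel index recorded in the sidecar
#' @return `path`, invisibly
#' @export
write_signal <- function(x, path, fs, channel = 0L) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 8, endian = "little")
  jsonlite::write_json(
    list(fs_hz = fs, units = "V", n_samples = length(x),
         channel = as.integer(channel)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a voltage series written by [write_signal()]
#'
#' Also reads one-sample-per-line delimited text when `path` ends in `.txt`
#' or `.csv` (sidecar still required for the sampling rate).
#'
#' @param path file path
#' @return list with `signal`, `fs`, `channel`
#' @export
read_signal <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  x <- if (grepl("\\.(txt|csv)$", path)) {
    as.numeric(readLines(path))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, numeric(), n = meta$n_samples, size = 8, endian = "little")
  }
  if (length(x) != meta$n_samples) {
    stop("signal length does not match sidecar")
  }
  list(signal = x, fs = meta$fs_hz, channel = meta$channel)
}

#' Write ground-truth spike annotations as CSV
#'
#' Two columns: `time_s`, `unit_label`.
#'
#' @param rec an `annotated_recording`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_truth <- function(rec, path) {
  stopifnot(inherits(rec, "annotated_recording"))
  utils::write.csv(
    data.frame(time_s = rec$truth_times, unit_label = rec$truth_labels),
    path, row.names = FALSE)
  invisible(path)
}

#' Read ground-truth spike annotations from CSV
#'
#' @param path CSV with columns `time_s`, `unit_label`
#' @return data.frame with those columns, sorted by time
#' @export
read_truth <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "unit_label") %in% names(d))) {
    stop("truth file must have columns time_s, unit_label")
  }
  d[order(d$time_s), , drop = FALSE]
}
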