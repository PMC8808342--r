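#' Write / read an ECG waveform file
#'
#' Two-column delimited text (time_s, amplitude) with a comment header
#' carrying the sampling rate, one file per night.
#'
#' @param record a \code{\link{waveform_record}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_ecg_file <- function(record, path) {
  stopifnot(inherits(record, "waveform_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz: %.10g", record$sampling_rate_hz), con)
  writeLines(sprintf("# start_time_s: %.10g", record$start_time_s), con)
  writeLines("time_s\tamplitude", con)
  tt <- record$start_time_s + (seq_along(record$samples) - 1) /
    record$sampling_rate_hz
  writeLines(paste(format_num(tt), format_num(record$samples), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_ecg_file
#' @param path file to read.
#' @export
read_ecg_file <- function(path) {
  hdr <- readLines(path, n = 2L)
  fs <- as.numeric(sub("^#\\s*sampling_rate_hz:\\s*", "", hdr[1]))
  t0 <- as.numeric(sub("^#\\s*start_time_s:\\s*", "", hdr[2]))
  if (!is.finite(fs))
    stop("read_ecg_file: missing '# sampling_rate_hz:' header in ", path,
         call. = FALSE)
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  waveform_record(d$amplitude, fs, start_time_s = if (is.finite(t0)) t0 else 0)
}

#' Write / read a wearable IBI file
#'
#' Three-column delimited text (beat_time_s, nn_ms, valid in {0,1})
#' emulating a cloud interbeat-interval export.
#'
#' @param nn an \code{\link{nn_series}}.
#' @param path file path.
#' @return \code{path} invisibly (write) or an \code{nn_series} (read).
#' @export
write_ibi_file <- function(nn, path) {
  stopifnot(inherits(nn, "nn_series"))
  d <- data.frame(beat_time_s = nn$beat_times_s[-1],
                  nn_ms = nn$nn_ms, valid = as.integer(nn$valid))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("beat_time_s\tnn_ms\tvalid", con)
  writeLines(paste(format_num(d$beat_time_s), format_num(d$nn_ms),
                   d$valid, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_ibi_file
#' @export
read_ibi_file <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  beats <- c(d$beat_time_s[1] - d$nn_ms[1] / 1000, d$beat_time_s)
  nn_series(beats, valid = d$valid == 1L, source = "wearable")
}

# deterministic full-precision numeric formatting for text outputs
format_num <- function(x) {
  out <- formatC(x, digits = 15, format = "g")
  out[is.na(x)] <- "NA"
  trimws(out)
}

#' Write a delimited table with an optional provenance header
#'
#' Tab-separated values with a header row; comment lines (prefixed
#' \code{#}) may carry a config hash for provenance.
#'
#' @param d a data frame.
#' @param path output path.
#' @param comment optional character vector of header comment lines
#'   (written as \code{# <line>}).
#' @return \code{path}, invisibly.
#' @export
write_tsv_with_header <- function(d, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  is_num <- vapply(d, is.numeric, logical(1))
  d2 <- d
  d2[is_num] <- lapply(d[is_num], format_num)
  writeLines(paste(names(d2), collapse = "\t"), con)
  if (nrow(d2))
    writeLines(do.call(paste, c(unname(as.list(d2)), sep = "\t")), con)
  invisible(path)
}

#' @rdname write_tsv_with_header
#' @export
read_tsv_with_header <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
}
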