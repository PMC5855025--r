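#' GSR recording container
#'
#' A single-channel skin-conductance recording: conductance samples in
#' microsiemens plus its sampling rate and labels. This is the object every
#' pipeline stage consumes and returns.
#'
#' @param samples numeric vector of conductance values (microsiemens).
#' @param fs sampling rate in Hz (> 0).
#' @param subject_id subject identifier (coerced to character).
#' @param condition condition label, one of `"normal"`, `"phone"`, `"text"`
#'   (or `NA` for unlabeled signals).
#' @return an object of class `gsr_recording` with fields `samples`, `fs`,
#'   `subject_id`, `condition`.
#' @examples
#' rec <- gsr_recording(4 + 0.1 * sin(seq(0, 10, by = 0.02)), fs = 50)
#' duration(rec)
#' @export
gsr_recording <- function(samples, fs, subject_id = NA_character_,
                          condition = NA_character_) {
  stop_if_not(is.numeric(fs) && length(fs) == 1 && fs > 0,
              "`fs` must be a single positive number")
  stop_if_not(is.numeric(samples) && length(samples) >= 2,
              "`samples` must be numeric with length >= 2")
  stop_if_not(all(is.finite(samples)), "`samples` must be finite")
  if (!is.na(condition)) {
    condition <- match.arg(condition, c("normal", "phone", "text"))
  }
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         subject_id = as.character(subject_id),
         condition = as.character(condition)),
    class = "gsr_recording"
  )
}

#' @export
print.gsr_recording <- function(x, ...) {
  cat(sprintf(
    "<gsr_recording> subject=%s condition=%s  %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$condition, length(x$samples), x$fs, duration(x)))
  cat(sprintf("  conductance range: %.3f .. %.3f uS\n",
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a [gsr_recording()].
#' @return duration in seconds (`n / fs`).
#' @export
duration <- function(rec) length(rec$samples) / rec$fs

#' Read / write a recording as CSV
#'
#' The on-disk exchange format is a two-column CSV, `time_s` and `eda_uS`.
#'
#' @param rec a [gsr_recording()].
#' @param path file path.
#' @param ... passed to [gsr_recording()] (labels) when reading.
#' @return `write_recording_csv` returns `path` invisibly;
#'   `read_recording_csv` returns a [gsr_recording()].
#' @export
write_recording_csv <- function(rec, path) {
  n <- length(rec$samples)
  df <- data.frame(time_s = (seq_len(n) - 1) / rec$fs, eda_uS = rec$samples)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path, ...) {
  df <- utils::read.csv(path)
  stop_if_not(all(c("time_s", "eda_uS") %in% names(df)),
              "CSV must have columns time_s, eda_uS")
  dt <- diff(df$time_s)
  fs <- 1 / stats::median(dt)
  gsr_recording(df$eda_uS, fs = fs, ...)
}
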