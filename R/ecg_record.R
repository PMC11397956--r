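#' Construct an ECG record
#'
#' An `ecg_record` is the substrate for R-peak detection: an ordered sequence
#' of voltage samples in microvolts, a nominal sampling rate, and the global
#' Unix-epoch time of the first sample. Sample `i` (1-based) is timestamped
#' `start_epoch_ms + (i - 1) * 1000 / fs` unless an explicit `time_ms` vector
#' is supplied (used by the packet reader when packets were dropped in
#' transit). No rescaling or filtering is ever applied by the constructor or
#' by any reader.
#'
#' @param samples numeric vector of voltages in microvolts (µV).
#' @param fs sampling rate in Hz (> 0).
#' @param start_epoch_ms Unix epoch milliseconds of the first sample.
#' @param source_label free-text provenance, e.g. `"criterion"`,
#'   `"chest_sensor"` or `"synthetic"`.
#' @param time_ms optional explicit per-sample epoch times (ms); must be
#'   strictly increasing and the same length as `samples`. If omitted, a
#'   uniform grid at `fs` is implied.
#' @param dropouts optional data frame of dropout segments with columns
#'   `start_ms`, `end_ms` (half-open, epoch ms) describing spans where no
#'   samples were received.
#'
#' @return An object of class `ecg_record`: a list with elements `samples`,
#'   `fs`, `start_epoch_ms`, `source_label`, and optionally `time_ms` and
#'   `dropouts`.
#' @seealso [read_criterion_ecg()], [read_packet_ecg()], [sample_times()]
#' @export
ecg_record <- function(samples, fs, start_epoch_ms,
                       source_label = "unknown",
                       time_ms = NULL, dropouts = NULL) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)")
  }
  if (length(samples) == 0L) stop("no samples")
  if (anyNA(samples) || !is.numeric(samples)) {
    stop("`samples` must be numeric with no missing values")
  }
  if (!is.null(time_ms)) {
    if (length(time_ms) != length(samples)) {
      stop("`time_ms` must have one entry per sample")
    }
    if (is.unsorted(time_ms, strictly = TRUE)) {
      stop("`time_ms` must be strictly increasing")
    }
    if (abs(time_ms[1L] - start_epoch_ms) > 1e-6) {
      stop("`time_ms[1]` must equal `start_epoch_ms`")
    }
  }
  structure(
    list(samples = as.numeric(samples), fs = fs,
         start_epoch_ms = as.numeric(start_epoch_ms),
         source_label = source_label,
         time_ms = time_ms, dropouts = dropouts),
    class = "ecg_record"
  )
}

#' Per-sample epoch times of an ECG record
#'
#' @param record an [ecg_record()].
#' @return numeric vector of Unix epoch milliseconds, one per sample.
#' @export
sample_times <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  if (!is.null(record$time_ms)) return(record$time_ms)
  record$start_epoch_ms + (seq_along(record$samples) - 1) * 1000 / record$fs
}

#' Duration of an ECG record in seconds
#' @param record an [ecg_record()].
#' @return span from first to one period past the last sample, in seconds.
#' @export
record_duration_s <- function(record) {
  tt <- sample_times(record)
  (tt[length(tt)] - tt[1L] + 1000 / record$fs) / 1000
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ECG record [%s]: %d samples @ %g Hz (%.1f s)\n",
              x$source_label, length(x$samples), x$fs, record_duration_s(x)))
  cat(sprintf("  start epoch: %.0f ms; voltage range [%.1f, %.1f] uV\n",
              x$start_epoch_ms, min(x$samples), max(x$samples)))
  if (!is.null(x$dropouts) && nrow(x$dropouts) > 0L) {
    cat(sprintf("  %d dropout segment(s), total %.0f ms\n",
                nrow(x$dropouts),
                sum(x$dropouts$end_ms - x$dropouts$start_ms)))
  }
  invisible(x)
}

#' @export
plot.ecg_record <- function(x, from_s = 0, to_s = NULL, ...) {
  tt <- (sample_times(x) - x$start_epoch_ms) / 1000
  if (is.null(to_s)) to_s <- min(max(tt), from_s + 10)
  keep <- tt >= from_s & tt <= to_s
  graphics::plot(tt[keep], x$samples[keep], type = "l",
                 xlab = "time (s)", ylab = "voltage (uV)",
                 main = sprintf("ECG [%s]", x$source_label), ...)
  invisible(x)
}
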