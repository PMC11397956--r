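#' Construct an RR-interval series
#'
#' The common currency of all device comparisons: per-beat global timestamps
#' and the RR' intervals between consecutive beats,
#' `rr_ms[i] = beat_epoch_ms[i + 1] - beat_epoch_ms[i]`. Some commercial
#' RR exports emit a sentinel code (5000 ms) when no beat was detected in the
#' preceding 5 s window; sentinel entries are not beats and are kept out of
#' `beat_epoch_ms`/`rr_ms`, with their count and timestamps retained.
#'
#' @param beat_epoch_ms strictly increasing beat times, Unix epoch ms.
#' @param rr_ms optional RR' intervals (ms); defaults to
#'   `diff(beat_epoch_ms)`. Must be positive and of length
#'   `length(beat_epoch_ms) - 1`.
#' @param sentinel_times_ms epoch times (ms) at which sentinel (no-detection)
#'   codes were emitted, if any.
#' @param source_label free-text provenance.
#' @return An object of class `rr_series`.
#' @export
rr_series <- function(beat_epoch_ms, rr_ms = NULL,
                      sentinel_times_ms = numeric(0),
                      source_label = "unknown") {
  beat_epoch_ms <- as.numeric(beat_epoch_ms)
  if (length(beat_epoch_ms) > 1L &&
      is.unsorted(beat_epoch_ms, strictly = TRUE)) {
    stop("beat times must be strictly increasing")
  }
  if (is.null(rr_ms)) rr_ms <- diff(beat_epoch_ms)
  rr_ms <- as.numeric(rr_ms)
  if (length(rr_ms) != max(0L, length(beat_epoch_ms) - 1L)) {
    stop("`rr_ms` must have length(beat_epoch_ms) - 1 entries")
  }
  if (any(rr_ms <= 0)) stop("RR' intervals must be positive")
  structure(
    list(beat_epoch_ms = beat_epoch_ms, rr_ms = rr_ms,
         sentinel_times_ms = as.numeric(sentinel_times_ms),
         source_label = source_label),
    class = "rr_series"
  )
}

#' Number of beats in an RR series
#' @param x an [rr_series()].
#' @return integer beat count.
#' @export
n_beats <- function(x) {
  stopifnot(inherits(x, "rr_series"))
  length(x$beat_epoch_ms)
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("RR' series [%s]: %d beats, %d intervals",
              x$source_label, n_beats(x), length(x$rr_ms)))
  if (length(x$sentinel_times_ms) > 0L) {
    cat(sprintf(", %d sentinel code(s)", length(x$sentinel_times_ms)))
  }
  cat("\n")
  if (length(x$rr_ms) > 0L) {
    cat(sprintf("  RR' mean %.1f ms, SD %.1f ms, range [%.0f, %.0f] ms\n",
                mean(x$rr_ms), stats::sd(x$rr_ms),
                min(x$rr_ms), max(x$rr_ms)))
  }
  invisible(x)
}

#' Bundle synchronised device streams for one activity
#'
#' Groups the criterion ECG with whichever device streams were recorded
#' (chest-sensor ECG and/or an RR-interval export), all on Unix-epoch time.
#'
#' @param criterion an [ecg_record()] from the criterion system.
#' @param device_ecg optional [ecg_record()] from a chest sensor.
#' @param device_rr optional [rr_series()] from an RR-interval device.
#' @param activity_label one of `"rest_pre"`, `"incremental"`, `"rest_post"`.
#' @param subject optional subject identifier.
#' @param mode optional exercise mode (`"running"` or `"cycling"`).
#' @return An object of class `stream_bundle`.
#' @export
stream_bundle <- function(criterion, device_ecg = NULL, device_rr = NULL,
                          activity_label = c("rest_pre", "incremental",
                                             "rest_post"),
                          subject = NA_character_, mode = NA_character_) {
  activity_label <- match.arg(activity_label)
  stopifnot(inherits(criterion, "ecg_record"))
  if (is.null(device_ecg) && is.null(device_rr)) {
    stop("at least one device stream must be present")
  }
  if (!is.null(device_ecg)) stopifnot(inherits(device_ecg, "ecg_record"))
  if (!is.null(device_rr)) stopifnot(inherits(device_rr, "rr_series"))
  structure(
    list(criterion = criterion, device_ecg = device_ecg,
         device_rr = device_rr, activity_label = activity_label,
         subject = subject, mode = mode),
    class = "stream_bundle"
  )
}

#' @export
print.stream_bundle <- function(x, ...) {
  cat(sprintf("Stream bundle: subject %s, %s, activity %s\n",
              x$subject, x$mode, x$activity_label))
  print(x$criterion)
  if (!is.null(x$device_ecg)) print(x$device_ecg)
  if (!is.null(x$device_rr)) print(x$device_rr)
  invisible(x)
}
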