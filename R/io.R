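# Stream dialects:
#  * criterion ECG: plain text, header "start_epoch_ms=<int>", one uV value
#    per row, 1000 Hz unless stated otherwise.
#  * chest-sensor ECG: CSV of 16-sample packets with a relative timestamp
#    per packet and a global start epoch on a leading comment line.
#  * RR device: CSV with FIT-epoch per-beat timestamps and RR' values (ms);
#    5000 ms entries are no-detection sentinels, not beats.

# Calendar seconds from 1970-01-01T00:00:00Z to 1989-12-31T00:00:00Z
# (7304 days: 19 full years with 5 leap days, plus 364 days of 1989).
FIT_OFFSET_S <- 631065600

#' Convert FIT-epoch seconds to Unix epoch milliseconds
#'
#' Activity-file (`.fit`) exports timestamp events in seconds since midnight
#' on 31 December 1989 UTC (the "FIT epoch") rather than the Unix epoch.
#' The calendar offset between the two origins is 631,065,600 s.
#'
#' @param fit_ts_s timestamp(s) in seconds since the FIT epoch (>= 0; may be
#'   fractional).
#' @return Unix epoch milliseconds, `(fit_ts_s + 631065600) * 1000`.
#' @seealso [unix_ms_to_fit_epoch()]
#' @export
fit_epoch_to_unix_ms <- function(fit_ts_s) {
  if (any(fit_ts_s < 0)) stop("FIT timestamps must be non-negative")
  (as.numeric(fit_ts_s) + FIT_OFFSET_S) * 1000
}

#' Convert Unix epoch milliseconds to FIT-epoch seconds
#' @param unix_ms Unix epoch milliseconds.
#' @return seconds since the FIT epoch (midnight 31 December 1989 UTC).
#' @export
unix_ms_to_fit_epoch <- function(unix_ms) {
  as.numeric(unix_ms) / 1000 - FIT_OFFSET_S
}

parse_start_header <- function(line, path) {
  m <- regmatches(line, regexec("start_epoch_ms\\s*=\\s*(-?[0-9.]+)", line))[[1]]
  if (length(m) < 2L) {
    stop(sprintf("%s: missing or unparseable start_epoch_ms header", path))
  }
  as.numeric(m[2L])
}

#' Read a criterion ECG text export
#'
#' The criterion (three-lead laboratory) system exports a plain-text file:
#' a header line carrying the recording-start global timestamp, then one
#' voltage value per row. Samples are taken as uniformly spaced at `fs`;
#' no resampling or filtering is applied on load.
#'
#' @param path file path.
#' @param fs sampling rate in Hz (default 1000, the criterion system rate).
#' @return an [ecg_record()] with `source_label = "criterion"`.
#' @export
read_criterion_ecg <- function(path, fs = 1000) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop(sprintf("%s: empty file", path))
  start_ms <- parse_start_header(lines[1L], path)
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) stop(sprintf("%s: no samples", path))
  v <- suppressWarnings(as.numeric(body))
  if (anyNA(v)) {
    bad <- which(is.na(v))[1L]
    stop(sprintf("%s: non-numeric voltage at data row %d", path, bad))
  }
  ecg_record(v, fs = fs, start_epoch_ms = start_ms,
             source_label = "criterion")
}

#' Write a criterion ECG text export
#'
#' Emits the same dialect [read_criterion_ecg()] consumes, bit-exactly
#' round-trippable (voltages are printed at full precision).
#'
#' @param record an [ecg_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_criterion_ecg <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("start_epoch_ms=%s",
                     format(record$start_epoch_ms, scientific = FALSE)), con)
  writeLines(format(record$samples, digits = 17, trim = TRUE,
                    scientific = FALSE), con)
  invisible(path)
}

#' Read a packetised chest-sensor ECG export
#'
#' The chest sensor transmits voltage in packets of 16 samples (µV), each
#' packet tagged with a relative timestamp (ms since device activation); a
#' global start epoch recorded at capture start anchors the stream on Unix
#' time. The packet timestamp marks the packet's first sample and samples
#' are spaced at the nominal period `1000 / fs` ms. Gaps between consecutive
#' packet timestamps exceeding 1.5 packet durations are recorded as dropout
#' segments in the returned record.
#'
#' @param path CSV path: a leading `# start_epoch_ms=<int>` comment line,
#'   then a header row and columns `relative_timestamp_ms, v0..v15`.
#' @param fs sampling rate in Hz (default 500, the chest-sensor rate).
#' @return an [ecg_record()] with `source_label = "chest_sensor"`; when
#'   packets were dropped the record carries explicit `time_ms` and a
#'   `dropouts` table (half-open epoch-ms segments).
#' @export
read_packet_ecg <- function(path, fs = 500) {
  first <- readLines(path, n = 1L, warn = FALSE)
  start_ms <- parse_start_header(first, path)
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  vcols <- grep("^v[0-9]+$", names(df), value = TRUE)
  if (length(vcols) != 16L) {
    stop(sprintf("%s: expected 16 voltage columns per packet, found %d",
                 path, length(vcols)))
  }
  if (nrow(df) == 0L) stop(sprintf("%s: no samples", path))
  vcols <- vcols[order(as.integer(sub("^v", "", vcols)))]
  rel <- as.numeric(df$relative_timestamp_ms)
  if (anyNA(rel)) stop(sprintf("%s: non-numeric packet timestamp", path))
  if (length(rel) > 1L && is.unsorted(rel, strictly = TRUE)) {
    stop(sprintf("%s: packet timestamps must be strictly increasing", path))
  }
  vm <- as.matrix(df[vcols])
  if (anyNA(vm)) stop(sprintf("%s: packet with missing voltage value", path))
  period <- 1000 / fs
  packet_dur <- 16 * period
  # per-sample times from per-packet anchors
  time_rel <- rep(rel, each = 16L) + rep.int(0:15, length(rel)) * period
  samples <- as.numeric(t(vm))
  start_epoch <- start_ms + rel[1L]
  gaps <- diff(rel)
  gap_idx <- which(gaps > 1.5 * packet_dur)
  dropouts <- NULL
  time_ms <- NULL
  if (length(gap_idx) > 0L) {
    dropouts <- data.frame(
      start_ms = start_ms + rel[gap_idx] + packet_dur,
      end_ms = start_ms + rel[gap_idx + 1L]
    )
    time_ms <- start_ms + time_rel
  }
  ecg_record(samples, fs = fs, start_epoch_ms = start_epoch,
             source_label = "chest_sensor",
             time_ms = time_ms, dropouts = dropouts)
}

#' Write a packetised chest-sensor ECG export
#'
#' @param record an [ecg_record()] whose length is a multiple of 16 (trailing
#'   samples short of a full packet are not written).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_packet_ecg <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  tt <- sample_times(record)
  n_pkt <- length(record$samples) %/% 16L
  if (n_pkt == 0L) stop("record shorter than one 16-sample packet")
  idx <- seq_len(n_pkt * 16L)
  vm <- matrix(record$samples[idx], ncol = 16L, byrow = TRUE)
  rel <- tt[seq(1L, by = 16L, length.out = n_pkt)] - record$start_epoch_ms
  df <- data.frame(relative_timestamp_ms = rel)
  colnames(vm) <- paste0("v", 0:15)
  df <- cbind(df, as.data.frame(vm))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# start_epoch_ms=%s",
                     format(record$start_epoch_ms, scientific = FALSE)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an RR-interval device export
#'
#' Consumes the converted CSV of an RR-interval device (`fit_timestamp_s`,
#' `rr_ms`, optionally `hr_bpm` which is ignored for computation). FIT-epoch
#' timestamps are converted to Unix epoch milliseconds via
#' [fit_epoch_to_unix_ms()]. Each row's timestamp marks the beat *ending*
#' its RR' interval; the beat opening the first interval is reconstructed at
#' `t[1] - rr[1]`. Entries equal to `sentinel_ms` are no-detection codes:
#' they are flagged and excluded from the interval series.
#'
#' @param path CSV path.
#' @param sentinel_ms sentinel value marking a non-detection (default 5000,
#'   i.e. no beat found in the preceding 5 s).
#' @return an [rr_series()].
#' @export
read_rr_stream <- function(path, sentinel_ms = 5000) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("fit_timestamp_s", "rr_ms") %in% names(df))) {
    stop(sprintf("%s: expected columns fit_timestamp_s, rr_ms", path))
  }
  ts_ms <- fit_epoch_to_unix_ms(as.numeric(df$fit_timestamp_s))
  if (length(ts_ms) > 1L && any(diff(ts_ms) <= 0)) {
    stop(sprintf("%s: timestamps must be strictly increasing", path))
  }
  rr <- as.numeric(df$rr_ms)
  is_sent <- rr == sentinel_ms
  rr_ok <- rr[!is_sent]
  ts_ok <- ts_ms[!is_sent]
  if (length(ts_ok) == 0L) {
    return(rr_series(numeric(0), rr_ms = numeric(0),
                     sentinel_times_ms = ts_ms[is_sent],
                     source_label = "rr_device"))
  }
  # beat times: timestamp closes its interval; prepend the opening beat.
  # After a sentinel (or any detection gap) the device-reported RR' no
  # longer equals the time difference to the previous retained beat, so
  # beats are anchored on the file's own timestamps.
  beats <- c(ts_ok[1L] - rr_ok[1L], ts_ok)
  if (is.unsorted(beats, strictly = TRUE)) {
    stop(sprintf("%s: first RR' interval inconsistent with timestamps", path))
  }
  structure(
    list(beat_epoch_ms = beats, rr_ms = rr_ok,
         sentinel_times_ms = ts_ms[is_sent],
         source_label = "rr_device"),
    class = "rr_series"
  )
}

#' Write an RR-interval device export
#'
#' Emits the dialect [read_rr_stream()] consumes. One row per RR' interval,
#' timestamped at the beat closing the interval (FIT-epoch seconds, 3
#' decimals); sentinel codes are written at their recorded times.
#'
#' @param rr an [rr_series()].
#' @param path output CSV path.
#' @param sentinel_ms sentinel code value (default 5000).
#' @return `path`, invisibly.
#' @export
write_rr_stream <- function(rr, path, sentinel_ms = 5000) {
  stopifnot(inherits(rr, "rr_series"))
  ts <- rr$beat_epoch_ms[-1L]
  val <- rr$rr_ms
  if (length(rr$sentinel_times_ms) > 0L) {
    ts <- c(ts, rr$sentinel_times_ms)
    val <- c(val, rep(sentinel_ms, length(rr$sentinel_times_ms)))
    o <- order(ts)
    ts <- ts[o]
    val <- val[o]
  }
  hr <- ifelse(val == sentinel_ms, NA_real_, round(60000 / val, 1))
  df <- data.frame(
    fit_timestamp_s = sprintf("%.3f", unix_ms_to_fit_epoch(ts)),
    rr_ms = format(val, digits = 15, trim = TRUE, scientific = FALSE),
    hr_bpm = hr
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Truncate an ECG record at the first disconnection
#'
#' Electrode or radio disconnection shows up as an almost absent voltage and
#' a flat signal. This scans sliding windows (stepped by half a window) and
#' cuts the record at the start of the first window whose peak-to-peak
#' voltage range falls below `flat_range_uv`; only data before the cut are
#' kept. Records with no flat window are returned unchanged.
#'
#' @param record an [ecg_record()].
#' @param window_s window length in seconds (default 2).
#' @param flat_range_uv peak-to-peak range (µV) below which a window counts
#'   as flat (default 50).
#' @return a list with elements `record` (the retained prefix, or `NULL` if
#'   the record is flat from the start) and `report` (list: `cut`,
#'   `cut_epoch_ms`, `reason`).
#' @export
truncate_at_disconnection <- function(record, window_s = 2,
                                      flat_range_uv = 50) {
  stopifnot(inherits(record, "ecg_record"), window_s > 0)
  n <- length(record$samples)
  win <- max(2L, as.integer(round(window_s * record$fs)))
  step <- max(1L, win %/% 2L)
  starts <- seq(1L, n, by = step)
  tt <- sample_times(record)
  for (s in starts) {
    e <- min(n, s + win - 1L)
    seg <- record$samples[s:e]
    if ((max(seg) - min(seg)) < flat_range_uv) {
      if (s == 1L) {
        return(list(record = NULL,
                    report = list(cut = TRUE, cut_epoch_ms = tt[1L],
                                  reason = "flat from start (total disconnection)")))
      }
      prefix <- ecg_record(record$samples[1:(s - 1L)], fs = record$fs,
                           start_epoch_ms = record$start_epoch_ms,
                           source_label = record$source_label,
                           time_ms = if (!is.null(record$time_ms))
                             record$time_ms[1:(s - 1L)] else NULL)
      return(list(record = prefix,
                  report = list(cut = TRUE, cut_epoch_ms = tt[s],
                                reason = sprintf(
                                  "flat window (<%g uV p-p over %g s)",
                                  flat_range_uv, window_s))))
    }
    if (e == n) break
  }
  list(record = record,
       report = list(cut = FALSE, cut_epoch_ms = NA_real_,
                     reason = "no cut"))
}
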