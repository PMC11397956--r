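# Multi-stream synchronisation.
#
# Streams already carry global Unix-epoch timestamps, so coarse alignment
# reduces to the residual start-time discrepancy between devices (clock
# error). The refinement step resamples both RR' sequences onto a common
# 250 ms tachogram grid and scans candidate offsets for the maximum of the
# normalised cross-correlation; correlating tachograms (RR' value against
# time) rather than beat indices keeps missed beats from de-phasing the
# comparison.

#' Coarse alignment of two RR series
#'
#' Returns the residual start-time discrepancy between the streams,
#' `a` minus `b` at the start of their overlap — an additive offset bound
#' for [refine_by_rr_correlation()]. With both streams on Unix-epoch time
#' this is 0 up to device clock error.
#'
#' @param a,b [rr_series()] objects on the same epoch convention.
#' @return offset bound in ms (add to `b`'s times to land near `a`'s).
#' @export
coarse_align <- function(a, b) {
  stopifnot(inherits(a, "rr_series"), inherits(b, "rr_series"))
  if (n_beats(a) == 0L || n_beats(b) == 0L) stop("empty RR series")
  a_span <- range(a$beat_epoch_ms)
  b_span <- range(b$beat_epoch_ms)
  slack <- 60000  # tolerate up to a minute of clock error when checking overlap
  if (b_span[1L] > a_span[2L] + slack || a_span[1L] > b_span[2L] + slack) {
    stop("no overlap between streams")
  }
  a$beat_epoch_ms[1L] - b$beat_epoch_ms[1L]
}

tachogram <- function(rr, grid_ms) {
  # piecewise-constant RR' value over time, sampled on grid_ms:
  # each interval's value holds from the beat closing it onwards
  stats::approx(x = rr$beat_epoch_ms[-1L], y = rr$rr_ms, xout = grid_ms,
                method = "constant", f = 0, rule = 1)$y
}

#' Refine stream alignment by tachogram cross-correlation
#'
#' Scans candidate offsets on a grid, correlating the two RR' tachograms
#' (piecewise-constant RR' resampled at `grid_ms`) over their overlap, and
#' returns the offset maximising the normalised cross-correlation, with
#' parabolic sub-step interpolation of the optimum. An alignment whose peak
#' correlation falls below `min_score` is returned with `verified = FALSE`.
#'
#' @param reference criterion-side [rr_series()].
#' @param device device-side [rr_series()].
#' @param search_ms half-range of candidate offsets in ms (default 30000).
#' @param step_ms offset grid step in ms (default 50).
#' @param grid_ms tachogram sampling interval in ms (default 250, resolving
#'   beats up to 240 bpm).
#' @param min_score minimum peak correlation for a verified alignment
#'   (default 0.5).
#' @return an object of class `alignment_result`: list with `offset_ms`
#'   (add to device times to map onto reference time), `score` (peak
#'   correlation), `search_ms`, `step_ms`, `verified`, and `n_overlap`
#'   (tachogram points correlated at the optimum).
#' @export
refine_by_rr_correlation <- function(reference, device,
                                     search_ms = 30000, step_ms = 50,
                                     grid_ms = 250, min_score = 0.5) {
  stopifnot(inherits(reference, "rr_series"), inherits(device, "rr_series"))
  if (length(reference$rr_ms) < 30L || length(device$rr_ms) < 30L) {
    stop("need at least 30 overlapping beats in each stream")
  }
  offsets <- seq(-search_ms, search_ms, by = step_ms)
  ref_lo <- reference$beat_epoch_ms[2L]
  ref_hi <- reference$beat_epoch_ms[n_beats(reference)]
  grid <- seq(ref_lo, ref_hi, by = grid_ms)
  # winsorize at median +/- 3 MAD: a missed beat doubles the local RR' and
  # would otherwise dominate the correlation as an uncorrelated outlier
  winsor <- function(x) {
    med <- stats::median(x, na.rm = TRUE)
    s <- stats::mad(x, na.rm = TRUE)
    if (is.na(s) || s == 0) return(x)
    pmin(pmax(x, med - 3 * s), med + 3 * s)
  }
  ref_tac <- winsor(tachogram(reference, grid))
  dev_t0 <- device$beat_epoch_ms
  scores <- vapply(offsets, function(off) {
    dev <- device
    dev$beat_epoch_ms <- dev_t0 + off
    dt <- winsor(tachogram(dev, grid))
    ok <- !is.na(ref_tac) & !is.na(dt)
    if (sum(ok) < 30L) return(NA_real_)
    if (stats::sd(ref_tac[ok]) == 0 || stats::sd(dt[ok]) == 0) {
      return(NA_real_)
    }
    stats::cor(ref_tac[ok], dt[ok])
  }, numeric(1))
  if (all(is.na(scores))) stop("no overlap between streams at any offset")
  best <- which.max(scores)
  best_off <- offsets[best]
  best_score <- scores[best]
  # parabolic refinement on the three points around the optimum; skipped
  # when the grid optimum is already an exact match (self-alignment)
  if (best_score < 1 - 1e-9 &&
      best > 1L && best < length(offsets) &&
      !is.na(scores[best - 1L]) && !is.na(scores[best + 1L])) {
    y1 <- scores[best - 1L]; y2 <- scores[best]; y3 <- scores[best + 1L]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) {
      delta <- 0.5 * (y1 - y3) / denom
      if (abs(delta) <= 1) best_off <- best_off + delta * step_ms
    }
  }
  n_overlap <- {
    dev <- device
    dev$beat_epoch_ms <- dev_t0 + offsets[best]
    dt <- tachogram(dev, grid)
    sum(!is.na(ref_tac) & !is.na(dt))
  }
  structure(
    list(offset_ms = best_off, score = best_score,
         search_ms = search_ms, step_ms = step_ms,
         verified = !is.na(best_score) && best_score >= min_score,
         n_overlap = n_overlap),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "Alignment: offset %+.1f ms (score %.3f over %d tachogram points) [%s]\n",
    x$offset_ms, x$score, x$n_overlap,
    if (x$verified) "verified" else "NOT verified"))
  invisible(x)
}

shift_times <- function(obj, offset_ms) {
  if (is.null(obj)) return(NULL)
  if (inherits(obj, "ecg_record")) {
    orig <- obj$start_epoch_ms
    obj$start_epoch_ms <- obj$start_epoch_ms + offset_ms
    if (!is.null(obj$time_ms)) obj$time_ms <- obj$time_ms + offset_ms
    if (!is.null(obj$dropouts)) {
      obj$dropouts$start_ms <- obj$dropouts$start_ms + offset_ms
      obj$dropouts$end_ms <- obj$dropouts$end_ms + offset_ms
    }
    attr(obj, "original_start_epoch_ms") <- orig
  } else if (inherits(obj, "rr_series")) {
    attr(obj, "original_beat_epoch_ms") <- obj$beat_epoch_ms
    obj$beat_epoch_ms <- obj$beat_epoch_ms + offset_ms
    if (length(obj$sentinel_times_ms) > 0L) {
      obj$sentinel_times_ms <- obj$sentinel_times_ms + offset_ms
    }
  }
  obj
}

#' Apply alignment offsets to a stream bundle
#'
#' Shifts every device-stream event time by its alignment offset, mapping
#' the bundle onto the criterion timeline. RR' values are never altered —
#' only event times move; original times are retained as attributes.
#'
#' @param bundle a [stream_bundle()].
#' @param ecg_alignment,rr_alignment `alignment_result` objects for the
#'   chest-sensor ECG and the RR device (whichever streams are present).
#' @param override apply even if an alignment is not verified
#'   (default `FALSE`; unverified alignments are refused otherwise).
#' @return the bundle with device times shifted.
#' @export
apply_alignment <- function(bundle, ecg_alignment = NULL,
                            rr_alignment = NULL, override = FALSE) {
  stopifnot(inherits(bundle, "stream_bundle"))
  check <- function(al, what) {
    if (is.null(al)) return(invisible(NULL))
    stopifnot(inherits(al, "alignment_result"))
    if (!al$verified && !override) {
      stop(sprintf(
        "%s alignment not verified (score %.3f); pass override = TRUE to force",
        what, al$score))
    }
  }
  check(ecg_alignment, "device ECG")
  check(rr_alignment, "RR device")
  if (!is.null(ecg_alignment) && !is.null(bundle$device_ecg)) {
    bundle$device_ecg <- shift_times(bundle$device_ecg,
                                     ecg_alignment$offset_ms)
  }
  if (!is.null(rr_alignment) && !is.null(bundle$device_rr)) {
    bundle$device_rr <- shift_times(bundle$device_rr,
                                    rr_alignment$offset_ms)
  }
  bundle
}
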