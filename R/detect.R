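# Exercise-robust R-peak detection.
#
# Pipeline: segment the record into short intervals -> in each interval run
# two independent passes (upright R lobe, and the same search on the negated
# signal for S-dominant complexes) with a voltage-sorted iterative threshold
# -> merge the branches -> flag statistically abnormal RR' intervals ->
# re-search the raw signal locally around flagged gaps with a relaxed
# threshold -> iterate until no further repairs.

#' Detector configuration
#'
#' Tunable parameters of [detect_rpeaks()]. All defaults are exposed so the
#' algorithm is fully reproducible from a config object.
#'
#' @param interval_s segmentation window length in seconds. Short enough
#'   that heart rate drifts little within a window during incremental
#'   exercise ramps (default 10).
#' @param refractory_ms minimum physiological gap between QRS complexes
#'   (default 200 ms); candidate events closer than this are the same beat.
#' @param threshold_quantile_start initial voltage quantile at which the
#'   per-interval threshold search starts (default 0.99).
#' @param threshold_quantile_min lowest quantile the search may reach
#'   (default 0.50).
#' @param plausible_bpm admissible beat-rate range used to accept a
#'   threshold (default `c(30, 240)`).
#' @param noise_floor_mads minimum accepted threshold, as a multiple of the
#'   window's robust scale (MAD of the centred voltage; default 5). Windows
#'   containing only noise never present a supra-floor plausible threshold
#'   and yield no candidates.
#' @param anomaly_k multiplier on the local median absolute deviation beyond
#'   which an RR' interval is flagged as abnormal (default 4).
#' @param anomaly_window rolling window (number of intervals) for the local
#'   median/MAD (default 11, an odd number).
#' @param ratio_high,ratio_low RR' ratio gates: intervals above
#'   `ratio_high` x local median suggest a missed beat, below `ratio_low` x
#'   an extra beat (defaults 1.8 and 0.55).
#' @param search_halfwidth_ms half-width of the local re-search window
#'   around an anomalous gap (default 150 ms).
#' @param repair_threshold_frac fraction of the interval's detection
#'   threshold a re-searched candidate must exceed (default 0.5).
#' @param max_iterations cap on detect/repair refinement iterations
#'   (default 5).
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(interval_s = 10,
                            refractory_ms = 200,
                            threshold_quantile_start = 0.99,
                            threshold_quantile_min = 0.50,
                            plausible_bpm = c(30, 240),
                            noise_floor_mads = 5,
                            anomaly_k = 4,
                            anomaly_window = 11,
                            ratio_high = 1.8,
                            ratio_low = 0.55,
                            search_halfwidth_ms = 150,
                            repair_threshold_frac = 0.5,
                            max_iterations = 5) {
  stopifnot(interval_s > 0, refractory_ms >= 0,
            threshold_quantile_start > threshold_quantile_min,
            threshold_quantile_start < 1,
            length(plausible_bpm) == 2L, all(plausible_bpm > 0),
            noise_floor_mads >= 0, anomaly_k > 0, anomaly_window >= 3,
            ratio_high > 1, ratio_low < 1, ratio_low > 0,
            search_halfwidth_ms > 0,
            repair_threshold_frac > 0, max_iterations >= 1)
  structure(as.list(environment()), class = "detector_config")
}

#' Partition an ECG record into detection intervals
#'
#' Contiguous, non-overlapping, half-open index ranges covering every
#' sample; the last range may be shorter. The sampling rate measured from
#' the actual timestamps is attached per range (it can differ from the
#' nominal rate across dropout gaps).
#'
#' @param record an [ecg_record()].
#' @param interval_s window length in seconds.
#' @return data frame with columns `start_idx`, `end_idx` (inclusive,
#'   1-based), `start_ms`, `end_ms`, `fs_measured`.
#' @export
segment_intervals <- function(record, interval_s) {
  stopifnot(inherits(record, "ecg_record"), interval_s > 0)
  n <- length(record$samples)
  if (n < 1L) stop("record has no samples")
  tt <- sample_times(record)
  width <- interval_s * 1000
  bin <- floor((tt - tt[1L]) / width)
  starts <- which(c(TRUE, diff(bin) != 0))
  ends <- c(starts[-1L] - 1L, n)
  fs_measured <- vapply(seq_along(starts), function(i) {
    s <- starts[i]; e <- ends[i]
    if (e == s) record$fs else 1000 * (e - s) / (tt[e] - tt[s])
  }, numeric(1))
  data.frame(start_idx = starts, end_idx = ends,
             start_ms = tt[starts], end_ms = tt[ends],
             fs_measured = fs_measured)
}

# strict-rise local maxima above a threshold; plateau ties resolve to the
# earliest sample. Endpoints are never maxima.
local_maxima_above <- function(v, thr) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  cand <- i[v[i] > thr & v[i] > v[i - 1L] & v[i] >= v[i + 1L]]
  if (length(cand) < 2L) return(cand)
  # drop later members of equal-valued plateaus
  cand[c(TRUE, !(v[cand[-1L]] == v[cand[-length(cand)]] &
                   diff(cand) == 1L))]
}

# collapse candidate events closer than refractory_ms to the single largest
# (earliest on ties); events within a refractory window cannot be distinct
# beats.
collapse_refractory <- function(idx, times, values, refractory_ms) {
  if (length(idx) <= 1L) return(idx)
  keep <- integer(0)
  grp_start <- 1L
  for (j in 2:(length(idx) + 1L)) {
    if (j > length(idx) || times[j] - times[j - 1L] > refractory_ms) {
      grp <- grp_start:(j - 1L)
      keep <- c(keep, grp[which.max(values[grp])])
      grp_start <- j
    }
  }
  idx[keep]
}

#' Detect candidate peaks within one interval
#'
#' Implements the voltage-sorted iterative threshold: descending through
#' the sorted voltage tail in 1-percentile steps, each candidate threshold
#' implies an event count (supra-threshold local maxima, with events inside
#' one refractory window collapsed to their largest sample). The accepted
#' threshold is the highest one inside the widest stable plateau: the run
#' of consecutive thresholds yielding the same physiologically plausible
#' count that spans the largest voltage range. The plateau rule makes the
#' choice insensitive to amplitude modulation of individual QRS apexes
#' (overlapping T waves, baseline wander), which would otherwise let the
#' "highest plausible threshold" clip the weakest beats. The `"S"`
#' polarity runs the identical search on the negated signal to catch
#' inverted (S-dominant) complexes.
#'
#' @param samples voltage slice (µV).
#' @param times_ms per-sample epoch times for the slice.
#' @param polarity `"R"` (upright) or `"S"` (signal negated first).
#' @param config a [detector_config()].
#' @return list with `idx` (1-based indices into the slice), `time_ms`,
#'   `amplitude` (median-centred, on the searched polarity), `threshold`
#'   (accepted threshold, µV above the window median) and `quantile` used;
#'   empty `idx` when the window is flat or no threshold is plausible.
#' @export
detect_in_interval <- function(samples, times_ms, polarity = c("R", "S"),
                               config = detector_config()) {
  polarity <- match.arg(polarity)
  stopifnot(length(samples) == length(times_ms))
  v <- if (polarity == "S") -samples else samples
  v <- v - stats::median(v)
  empty <- list(idx = integer(0), time_ms = numeric(0),
                amplitude = numeric(0), threshold = NA_real_,
                quantile = NA_real_)
  if (length(v) < 3L || max(v) - min(v) == 0) return(empty)
  win_s <- (times_ms[length(times_ms)] - times_ms[1L]) / 1000
  if (win_s <= 0) return(empty)
  n_min <- max(1, floor(config$plausible_bpm[1L] * win_s / 60))
  n_max <- ceiling(config$plausible_bpm[2L] * win_s / 60)
  qs <- seq(config$threshold_quantile_start,
            config$threshold_quantile_min, by = -0.01)
  sv <- sort(v)  # one sort; quantiles read from the sorted vector
  nn <- length(sv)
  # all strict local maxima once; per-threshold work then touches only them
  mx <- local_maxima_above(v, -Inf)
  if (length(mx) == 0L) return(empty)
  mx_t <- times_ms[mx]
  mx_v <- v[mx]
  thr_q <- vapply(qs, function(q)
    sv[max(1L, min(nn, as.integer(ceiling(q * nn))))], numeric(1))
  noise_floor <- config$noise_floor_mads * stats::mad(v)
  counts <- integer(length(qs))
  for (j in seq_along(qs)) {
    if (thr_q[j] <= 0 || thr_q[j] < noise_floor) { counts[j] <- -1L; next }
    sel <- mx_v > thr_q[j]
    if (!any(sel)) { counts[j] <- 0L; next }
    keep <- collapse_refractory(which(sel), mx_t[sel], mx_v[sel],
                                config$refractory_ms)
    counts[j] <- length(keep)
  }
  plausible <- counts >= n_min & counts <= n_max
  if (!any(plausible)) return(empty)
  # runs of consecutive thresholds with identical plausible count
  run_id <- cumsum(c(TRUE, diff(counts) != 0 | diff(plausible) != 0))
  best_j <- NA_integer_
  best_span <- -Inf
  for (rid in unique(run_id[plausible])) {
    jj <- which(run_id == rid)
    span <- thr_q[jj[1L]] - thr_q[jj[length(jj)]]
    if (span > best_span) {  # ties resolve to the higher-threshold run
      best_span <- span
      best_j <- jj[1L]
    }
  }
  thr <- thr_q[best_j]
  sel <- mx_v > thr
  cand <- mx[collapse_refractory(which(sel), mx_t[sel], mx_v[sel],
                                 config$refractory_ms)]
  list(idx = cand, time_ms = times_ms[cand], amplitude = v[cand],
       threshold = thr, quantile = qs[best_j])
}

#' Merge upright- and inverted-pass candidates
#'
#' Candidates from the two branches within `refractory_ms` of one another
#' are the same beat and collapse to a single event. The retained time is
#' the branch member with the larger absolute (median-centred) amplitude —
#' the dominant lobe of the complex — with the upright branch preferred on
#' exact ties; the branch is recorded as `"R"`, `"S"`, or `"both"`.
#'
#' @param r_peaks,s_peaks candidate lists as returned by
#'   [detect_in_interval()] (fields `time_ms`, `amplitude`, optionally
#'   `idx`).
#' @param refractory_ms minimum inter-beat gap in ms.
#' @return data frame `time_ms`, `idx`, `amplitude`, `branch`, sorted by
#'   time, with consecutive events separated by more than `refractory_ms`.
#' @export
merge_branches <- function(r_peaks, s_peaks, refractory_ms = 200) {
  as_df <- function(p, br) {
    if (is.null(p) || length(p$time_ms) == 0L) {
      return(data.frame(time_ms = numeric(0), idx = integer(0),
                        amplitude = numeric(0), branch = character(0)))
    }
    data.frame(time_ms = p$time_ms,
               idx = if (!is.null(p$idx)) p$idx else NA_integer_,
               amplitude = abs(p$amplitude),
               branch = br)
  }
  all <- rbind(as_df(r_peaks, "R"), as_df(s_peaks, "S"))
  if (nrow(all) == 0L) return(all)
  all <- all[order(all$time_ms, all$branch), , drop = FALSE]
  out <- list()
  grp_start <- 1L
  n <- nrow(all)
  for (j in 2:(n + 1L)) {
    if (j > n || all$time_ms[j] - all$time_ms[j - 1L] > refractory_ms) {
      grp <- all[grp_start:(j - 1L), , drop = FALSE]
      best <- which.max(grp$amplitude)  # ties -> earliest; R sorts first
      row <- grp[best, , drop = FALSE]
      row$branch <- if (length(unique(grp$branch)) > 1L) "both"
        else grp$branch[1L]
      out[[length(out) + 1L]] <- row
      grp_start <- j
    }
    if (j > n) break
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag statistically abnormal RR' intervals
#'
#' An interval is abnormal when it deviates from the local rolling median
#' (window of `anomaly_window` intervals) by more than `anomaly_k` local
#' median absolute deviations, or exceeds `ratio_high` x / falls below
#' `ratio_low` x the local median. Gradual rate drift (an incremental
#' exercise ramp) moves the rolling median along with the data and is not
#' flagged; a single missed or spurious beat is. The local MAD is floored
#' at 5 ms so sampling-grid quantisation of otherwise steady rhythms cannot
#' trigger flags.
#'
#' @param peak_times_ms strictly increasing beat times (>= 3 beats).
#' @param config a [detector_config()].
#' @return data frame with one row per flagged interval: `interval` (index
#'   into `diff(peak_times_ms)`), `rr_ms`, `local_median_ms`, and `type`
#'   (`"missed_beat"` for long gaps, `"extra_beat"` for short ones). Zero
#'   rows when nothing is abnormal; with fewer than 3 beats a warning is
#'   raised and zero rows returned.
#' @export
flag_abnormal_rr <- function(peak_times_ms, config = detector_config()) {
  empty <- data.frame(interval = integer(0), rr_ms = numeric(0),
                      local_median_ms = numeric(0), type = character(0))
  if (length(peak_times_ms) < 3L) {
    warning("fewer than 3 peaks; no RR' statistics computed")
    return(empty)
  }
  rr <- diff(peak_times_ms)
  w <- min(config$anomaly_window, length(rr))
  if (w %% 2L == 0L) w <- w - 1L
  med <- if (w >= 3L) stats::runmed(rr, w, endrule = "median") else
    rep(stats::median(rr), length(rr))
  half <- w %/% 2L
  nrr <- length(rr)
  mad_loc <- vapply(seq_len(nrr), function(i) {
    lo <- max(1L, i - half); hi <- min(nrr, i + half)
    stats::median(abs(rr[lo:hi] - med[i]))
  }, numeric(1))
  mad_loc <- pmax(mad_loc, 5)  # quantisation floor
  dev_flag <- abs(rr - med) > config$anomaly_k * mad_loc
  hi_flag <- rr > config$ratio_high * med
  lo_flag <- rr < config$ratio_low * med
  flagged <- which((dev_flag | hi_flag | lo_flag))
  if (length(flagged) == 0L) return(empty)
  data.frame(interval = flagged, rr_ms = rr[flagged],
             local_median_ms = med[flagged],
             type = ifelse(rr[flagged] > med[flagged],
                           "missed_beat", "extra_beat"),
             rule = ifelse(hi_flag[flagged] | lo_flag[flagged],
                           "ratio", "mad"))
}

#' Re-search the raw signal around a target time
#'
#' Used to repair gaps flagged by [flag_abnormal_rr()]: within
#' `halfwidth_ms` of the target (typically the time a missing beat is
#' expected, interpolated from neighbouring RR' intervals), the best local
#' extremum of the median-centred signal — the larger of the upright and
#' inverted excursions — is accepted if it exceeds a relaxed fraction of
#' the enclosing interval's detection threshold.
#'
#' @param record an [ecg_record()].
#' @param target_epoch_ms centre of the search window.
#' @param halfwidth_ms search half-width in ms.
#' @param threshold the enclosing interval's detection threshold (µV above
#'   the window median).
#' @param relaxed_frac fraction of `threshold` the candidate must exceed
#'   (default 0.5).
#' @return list `idx`, `time_ms`, `amplitude` for the accepted candidate,
#'   or `NULL` when no candidate qualifies or the window lies outside the
#'   record (the latter with a warning).
#' @export
local_repeak_search <- function(record, target_epoch_ms, halfwidth_ms,
                                threshold, relaxed_frac = 0.5) {
  stopifnot(inherits(record, "ecg_record"))
  tt <- sample_times(record)
  lo <- target_epoch_ms - halfwidth_ms
  hi <- target_epoch_ms + halfwidth_ms
  if (hi < tt[1L] || lo > tt[length(tt)]) {
    warning("search window outside record span")
    return(NULL)
  }
  sel <- which(tt >= lo & tt <= hi)
  if (length(sel) < 3L) return(NULL)
  v <- record$samples[sel]
  vc <- v - stats::median(v)
  mag <- pmax(vc, -vc)
  best <- which.max(mag)
  if (!is.finite(threshold) || mag[best] < relaxed_frac * threshold) {
    return(NULL)
  }
  list(idx = sel[best], time_ms = tt[sel[best]], amplitude = vc[best])
}

#' Detect R-peaks in an ECG record
#'
#' Full detection pipeline: segment the record ([segment_intervals()]), run
#' the upright and inverted threshold searches per interval
#' ([detect_in_interval()]), merge the branches ([merge_branches()]), flag
#' abnormal RR' intervals ([flag_abnormal_rr()]) and repair them by local
#' re-search ([local_repeak_search()]) — inserting recovered beats into
#' long gaps and removing the weaker peak of implausibly short gaps — then
#' iterate; intervals with dense anomalies are re-detected with a lowered
#' starting quantile. Iteration stops when a pass makes no repairs or after
#' `max_iterations`. The procedure is fully deterministic.
#'
#' @param record an [ecg_record()] of at least 2 s.
#' @param config a [detector_config()].
#' @return an object of class `rpeak_detection`: list with `peaks` (data
#'   frame `peak_epoch_ms`, `sample_index`, `branch` — branch one of
#'   `"R"`, `"S"`, `"both"`, `"repaired"`), `diagnostics` (per-interval
#'   thresholds, branch counts, anomaly/repair counts, iterations run),
#'   `config`, and `record_info`.
#' @examples
#' beats <- generate_beat_times(protocol_profile(
#'   segments = data.frame(duration_s = 30, hr_start = 60, hr_end = 60,
#'                         label = "rest_pre", sdnn_ms = 0)))
#' rec <- synthesize_ecg(beats$beat_ms, fs = 500)
#' det <- detect_rpeaks(rec)
#' det
#' @export
detect_rpeaks <- function(record, config = detector_config()) {
  stopifnot(inherits(record, "ecg_record"))
  if (record_duration_s(record) < 2) stop("record shorter than 2 s")
  tt <- sample_times(record)
  segs <- segment_intervals(record, config$interval_s)
  n_seg <- nrow(segs)
  seg_quantile <- rep(config$threshold_quantile_start, n_seg)
  seg_threshold <- rep(NA_real_, n_seg)
  counts <- list(r_only = 0L, s_only = 0L, both = 0L)

  # each interval is detected with ~250 ms of context on both sides so a
  # QRS apex falling exactly on a boundary is still a local maximum;
  # candidates outside the core (half-open) range are discarded.
  ctx <- as.integer(ceiling(0.25 * record$fs))

  run_detection <- function() {
    peaks_list <- vector("list", n_seg)
    for (i in seq_len(n_seg)) {
      lo <- max(1L, segs$start_idx[i] - ctx)
      hi <- min(length(record$samples), segs$end_idx[i] + ctx)
      sel <- lo:hi
      cfg_i <- config
      cfg_i$threshold_quantile_start <- seg_quantile[i]
      r <- detect_in_interval(record$samples[sel], tt[sel], "R", cfg_i)
      s <- detect_in_interval(record$samples[sel], tt[sel], "S", cfg_i)
      upper <- if (i == n_seg) Inf else segs$start_ms[i + 1L]
      core <- function(p) {
        keep <- p$time_ms >= segs$start_ms[i] & p$time_ms < upper
        list(idx = p$idx[keep], time_ms = p$time_ms[keep],
             amplitude = p$amplitude[keep], threshold = p$threshold,
             quantile = p$quantile)
      }
      r <- core(r)
      s <- core(s)
      merged <- merge_branches(r, s, config$refractory_ms)
      thr_i <- suppressWarnings(max(c(r$threshold, s$threshold), na.rm = TRUE))
      seg_threshold[i] <<- if (is.finite(thr_i)) thr_i else NA_real_
      if (nrow(merged) > 0L) {
        merged$idx <- merged$idx + lo - 1L
        peaks_list[[i]] <- merged
      }
    }
    all <- do.call(rbind, peaks_list)
    if (is.null(all) || nrow(all) == 0L) {
      return(data.frame(time_ms = numeric(0), idx = integer(0),
                        amplitude = numeric(0), branch = character(0)))
    }
    # final cross-boundary refractory pass
    keep <- collapse_refractory(seq_len(nrow(all)), all$time_ms,
                                all$amplitude, config$refractory_ms)
    all[keep, , drop = FALSE]
  }

  peaks <- run_detection()
  total_inserted <- 0L
  total_removed <- 0L
  total_flagged <- 0L
  iterations <- 0L

  seg_of_time <- function(t) {
    i <- findInterval(t, segs$start_ms)
    min(max(i, 1L), n_seg)
  }

  for (iter in seq_len(config$max_iterations)) {
    iterations <- iter
    if (nrow(peaks) < 3L) break
    flags <- suppressWarnings(flag_abnormal_rr(peaks$time_ms, config))
    total_flagged <- total_flagged + nrow(flags)
    changed <- FALSE

    # long gaps: insert re-searched beats at interpolated positions.
    # Only ratio-gated flags trigger repair; MAD flags mark borderline
    # intervals for diagnostics but acting on them would chase ordinary
    # beat-to-beat variability.
    miss <- flags[flags$type == "missed_beat" & flags$rule == "ratio", ,
                  drop = FALSE]
    new_rows <- list()
    if (nrow(miss) > 0L) {
      for (r in seq_len(nrow(miss))) {
        gi <- miss$interval[r]
        t_left <- peaks$time_ms[gi]
        t_right <- peaks$time_ms[gi + 1L]
        n_missing <- max(1L, round(miss$rr_ms[r] / miss$local_median_ms[r]) - 1L)
        targets <- t_left + (seq_len(n_missing) / (n_missing + 1L)) *
          (t_right - t_left)
        for (tg in targets) {
          si <- seg_of_time(tg)
          cand <- local_repeak_search(record, tg, config$search_halfwidth_ms,
                                      seg_threshold[si],
                                      config$repair_threshold_frac)
          if (!is.null(cand)) {
            near <- min(abs(c(peaks$time_ms, vapply(new_rows, `[[`,
                                                    numeric(1), "time_ms")) -
                              cand$time_ms))
            if (near > config$refractory_ms) {
              new_rows[[length(new_rows) + 1L]] <-
                list(time_ms = cand$time_ms, idx = cand$idx,
                     amplitude = abs(cand$amplitude), branch = "repaired")
            }
          }
        }
      }
    }
    if (length(new_rows) > 0L) {
      add <- do.call(rbind, lapply(new_rows, function(x)
        data.frame(time_ms = x$time_ms, idx = x$idx,
                   amplitude = x$amplitude, branch = x$branch)))
      peaks <- rbind(peaks, add)
      peaks <- peaks[order(peaks$time_ms), , drop = FALSE]
      total_inserted <- total_inserted + nrow(add)
      changed <- TRUE
    }

    # short gaps: drop the weaker endpoint, but only when the removal
    # restores the local rhythm (the merged interval lands near the local
    # median) — a genuinely spurious beat splits one true interval in two.
    flags2 <- suppressWarnings(flag_abnormal_rr(peaks$time_ms, config))
    extra <- flags2[flags2$type == "extra_beat" & flags2$rule == "ratio", ,
                    drop = FALSE]
    if (nrow(extra) > 0L) {
      drop_idx <- integer(0)
      for (r in seq_len(nrow(extra))) {
        gi <- extra$interval[r]
        pair <- c(gi, gi + 1L)
        weaker <- pair[which.min(peaks$amplitude[pair])]
        if (weaker %in% drop_idx) next
        lo <- if (weaker > 1L) peaks$time_ms[weaker - 1L] else NA
        hi <- if (weaker < nrow(peaks)) peaks$time_ms[weaker + 1L] else NA
        if (!is.na(lo) && !is.na(hi)) {
          merged_rr <- hi - lo
          med <- extra$local_median_ms[r]
          if (merged_rr >= 0.7 * med && merged_rr <= 1.4 * med) {
            drop_idx <- c(drop_idx, weaker)
          }
        }
      }
      if (length(drop_idx) > 0L) {
        peaks <- peaks[-unique(drop_idx), , drop = FALSE]
        total_removed <- total_removed + length(unique(drop_idx))
        changed <- TRUE
      }
    }

    # lower the starting quantile where anomalies cluster, forcing a
    # re-detection of those intervals on the next pass
    if (nrow(flags) > 0L) {
      gap_times <- (peaks$time_ms[pmin(flags$interval, nrow(peaks))])
      seg_hits <- table(vapply(gap_times, seg_of_time, numeric(1)))
      dense <- as.integer(names(seg_hits))[seg_hits >= 3]
      dense <- dense[seg_quantile[dense] - 0.02 >
                       config$threshold_quantile_min]
      if (length(dense) > 0L && iter < config$max_iterations) {
        seg_quantile[dense] <- seg_quantile[dense] - 0.02
        redetected <- run_detection()
        if (nrow(redetected) != nrow(peaks) ||
            any(redetected$time_ms != peaks$time_ms)) {
          # keep repaired beats found so far that the re-detection missed
          rep_rows <- peaks[peaks$branch == "repaired", , drop = FALSE]
          peaks <- redetected
          for (r in seq_len(nrow(rep_rows))) {
            if (min(abs(peaks$time_ms - rep_rows$time_ms[r])) >
                config$refractory_ms) {
              peaks <- rbind(peaks, rep_rows[r, , drop = FALSE])
            }
          }
          peaks <- peaks[order(peaks$time_ms), , drop = FALSE]
          changed <- TRUE
        }
      }
    }

    if (!changed) break
  }

  branch_tab <- table(factor(peaks$branch,
                             levels = c("R", "S", "both", "repaired")))
  diagnostics <- list(
    n_intervals = n_seg,
    interval_thresholds = seg_threshold,
    interval_quantiles = seg_quantile,
    branch_counts = as.list(branch_tab),
    anomalies_flagged = total_flagged,
    repairs_inserted = total_inserted,
    repairs_removed = total_removed,
    iterations = iterations,
    usable = nrow(peaks) > 0L,
    note = if (nrow(peaks) == 0L)
      "no plausible threshold in any interval (flat or unusable record)"
    else NA_character_
  )
  structure(
    list(peaks = data.frame(peak_epoch_ms = peaks$time_ms,
                            sample_index = peaks$idx,
                            branch = peaks$branch,
                            amplitude = peaks$amplitude),
         diagnostics = diagnostics,
         config = config,
         record_info = list(source_label = record$source_label,
                            fs = record$fs,
                            n_samples = length(record$samples),
                            start_epoch_ms = record$start_epoch_ms)),
    class = "rpeak_detection"
  )
}

#' Beat times of a detection result
#' @param detection an `rpeak_detection` object.
#' @return numeric vector of peak epoch times (ms).
#' @export
peak_times <- function(detection) {
  stopifnot(inherits(detection, "rpeak_detection"))
  detection$peaks$peak_epoch_ms
}

#' RR' series derived from a detection result
#' @param detection an `rpeak_detection` object.
#' @return an [rr_series()].
#' @export
as_rr_series <- function(detection) {
  stopifnot(inherits(detection, "rpeak_detection"))
  rr_series(detection$peaks$peak_epoch_ms,
            source_label = detection$record_info$source_label)
}

#' @export
print.rpeak_detection <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("R-peak detection [%s]: %d peaks in %d interval(s)\n",
              x$record_info$source_label, nrow(x$peaks), d$n_intervals))
  cat(sprintf("  branches R/S/both/repaired: %d/%d/%d/%d\n",
              d$branch_counts$R, d$branch_counts$S, d$branch_counts$both,
              d$branch_counts$repaired))
  cat(sprintf("  anomalies flagged %d; repairs +%d/-%d; iterations %d\n",
              d$anomalies_flagged, d$repairs_inserted, d$repairs_removed,
              d$iterations))
  if (!d$usable) cat("  NOTE:", d$note, "\n")
  invisible(x)
}

#' @export
summary.rpeak_detection <- function(object, ...) {
  p <- object$peaks
  rr <- diff(p$peak_epoch_ms)
  out <- list(
    n_peaks = nrow(p),
    duration_s = object$record_info$n_samples / object$record_info$fs,
    mean_rr_ms = if (length(rr)) mean(rr) else NA_real_,
    sd_rr_ms = if (length(rr) > 1) stats::sd(rr) else NA_real_,
    mean_hr_bpm = if (length(rr)) mean(60000 / rr) else NA_real_,
    diagnostics = object$diagnostics
  )
  class(out) <- "summary.rpeak_detection"
  out
}

#' @export
print.summary.rpeak_detection <- function(x, ...) {
  cat(sprintf("%d peaks over %.1f s; mean RR' %.1f ms (SD %.1f), mean HR %.1f bpm\n",
              x$n_peaks, x$duration_s, x$mean_rr_ms, x$sd_rr_ms,
              x$mean_hr_bpm))
  cat(sprintf("anomalies %d, repairs +%d/-%d, iterations %d\n",
              x$diagnostics$anomalies_flagged,
              x$diagnostics$repairs_inserted,
              x$diagnostics$repairs_removed, x$diagnostics$iterations))
  invisible(x)
}

#' @export
plot.rpeak_detection <- function(x, record = NULL, from_s = 0, to_s = NULL,
                                 ...) {
  if (!is.null(record)) {
    plot(record, from_s = from_s, to_s = to_s, ...)
    tt0 <- record$start_epoch_ms
    pt <- (x$peaks$peak_epoch_ms - tt0) / 1000
    keep <- pt >= from_s & pt <= (to_s %||% Inf)
    graphics::abline(v = pt[keep], col = "red", lty = 3)
  } else {
    t_s <- (x$peaks$peak_epoch_ms - x$record_info$start_epoch_ms) / 1000
    rr <- diff(x$peaks$peak_epoch_ms)
    graphics::plot(t_s[-1L], rr, type = "p", pch = 20, cex = 0.4,
                   xlab = "time (s)", ylab = "RR' (ms)",
                   main = "Detected RR' tachogram", ...)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
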