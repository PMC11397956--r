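# Ground-truthed synthetic data emulating a rest / incremental-exercise /
# rest validation session: beat-time sequences from an instantaneous-HR
# protocol profile, ECG waveforms rendered from analytic QRS templates at
# either sampling rate, packetised chest-sensor streams, and degraded
# RR-device streams reproducing commercial-device failure modes (random and
# periodic missed beats, spurious beats, timing jitter, clock offset,
# no-detection sentinels).

#' Exercise protocol profile
#'
#' Defines the instantaneous heart-rate trajectory and short-term RR'
#' variability of a synthetic session. The default mirrors a laboratory
#' incremental session: 5 min seated rest, 6 min warm-up, a ~10 min
#' incremental ramp to near-maximal HR, 6 min cool-down, and 5 min final
#' rest, with resting HR ~65 bpm, peak ~195 bpm, and segment SDNN targets
#' descending from ~95 ms at rest to ~25 ms during post-exercise rest.
#'
#' @param segments data frame with columns `duration_s`, `hr_start`,
#'   `hr_end` (bpm, within 30-240), `label` (one of `"rest_pre"`,
#'   `"incremental"`, `"rest_post"`) and `sdnn_ms` (target white RR'
#'   jitter SD per segment).
#' @param seed integer random seed used by [generate_beat_times()].
#' @return an object of class `protocol_profile`.
#' @export
protocol_profile <- function(segments = NULL, seed = 1L) {
  if (is.null(segments)) {
    segments <- data.frame(
      duration_s = c(300, 360, 600, 360, 300),
      hr_start = c(65, 100, 125, 195, 105),
      hr_end = c(65, 125, 195, 110, 100),
      label = c("rest_pre", "incremental", "incremental", "incremental",
                "rest_post"),
      sdnn_ms = c(95, 55, 40, 40, 25)
    )
  }
  stopifnot(all(c("duration_s", "hr_start", "hr_end", "label",
                  "sdnn_ms") %in% names(segments)),
            all(segments$duration_s > 0),
            all(segments$hr_start >= 30 & segments$hr_start <= 240),
            all(segments$hr_end >= 30 & segments$hr_end <= 240),
            all(segments$sdnn_ms >= 0),
            all(segments$label %in% c("rest_pre", "incremental",
                                      "rest_post")))
  structure(list(segments = segments, seed = as.integer(seed)),
            class = "protocol_profile")
}

#' Generate ground-truth beat times from a protocol profile
#'
#' Integrate-and-fire on the piecewise-linear instantaneous HR trajectory:
#' each next beat falls one local RR' period after the previous one, plus
#' zero-mean Gaussian jitter targeting the segment's SDNN. RR' intervals
#' are floored at the larger of 250 ms and half the local period so jitter
#' can never produce a physiologically impossible beat. Reproducible under
#' the profile's seed.
#'
#' @param profile a [protocol_profile()].
#' @param start_epoch_ms epoch of session start (default
#'   1.7e12, an arbitrary 2023 date).
#' @return data frame with columns `beat_ms` (epoch ms, strictly
#'   increasing) and `activity` (segment label at the beat).
#' @export
generate_beat_times <- function(profile = protocol_profile(),
                                start_epoch_ms = 1.7e12) {
  stopifnot(inherits(profile, "protocol_profile"))
  seg <- profile$segments
  ends <- cumsum(seg$duration_s) * 1000
  starts <- c(0, ends[-length(ends)])
  total_ms <- ends[length(ends)]
  hr_at <- function(t_ms) {
    i <- findInterval(t_ms, starts, rightmost.closed = FALSE)
    i <- min(max(i, 1L), nrow(seg))
    frac <- (t_ms - starts[i]) / (seg$duration_s[i] * 1000)
    seg$hr_start[i] + frac * (seg$hr_end[i] - seg$hr_start[i])
  }
  seg_at <- function(t_ms) {
    min(max(findInterval(t_ms, starts), 1L), nrow(seg))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(profile$seed)
  t <- 0
  beats <- numeric(0)
  labels <- character(0)
  repeat {
    i <- seg_at(t)
    base_rr <- 60000 / hr_at(t)
    rr <- base_rr + stats::rnorm(1L, 0, seg$sdnn_ms[i])
    rr <- max(rr, 250, base_rr / 2)
    t <- t + rr
    if (t >= total_ms) break
    beats <- c(beats, t)
    labels <- c(labels, seg$label[seg_at(t)])
  }
  data.frame(beat_ms = start_epoch_ms + beats, activity = labels)
}

# save/restore the global RNG state so generators are seed-reproducible
# without clobbering the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' QRS morphology configuration
#'
#' Analytic QRS templates: a narrow Gaussian R lobe centred exactly on the
#' ground-truth beat time, a smaller opposite-sign S lobe half a QRS width
#' later, a broad low T wave, sinusoidal baseline wander and white Gaussian
#' noise. A negative `rs_ratio` inverts the whole complex (S-dominant
#' morphology) without moving the dominant-lobe apex off the beat time.
#'
#' @param qrs_amplitude_uv R-lobe amplitude in µV (default 1000).
#' @param qrs_width_ms total QRS width in ms (default 80).
#' @param rs_ratio R:S amplitude ratio; magnitude sets the S-lobe fraction
#'   (`1/|rs_ratio|`), sign flips the whole complex (default 4).
#' @param t_amplitude_uv T-wave amplitude (default 150).
#' @param wander_uv baseline-wander amplitude (default 0).
#' @param wander_hz baseline-wander frequency (default 0.3).
#' @param noise_sd_uv white-noise SD (default 0).
#' @return an object of class `morphology_config`.
#' @export
morphology_config <- function(qrs_amplitude_uv = 1000, qrs_width_ms = 80,
                              rs_ratio = 4, t_amplitude_uv = 150,
                              wander_uv = 0, wander_hz = 0.3,
                              noise_sd_uv = 0) {
  stopifnot(qrs_amplitude_uv > 0, qrs_width_ms > 0, rs_ratio != 0,
            is.finite(t_amplitude_uv), wander_uv >= 0, wander_hz > 0,
            noise_sd_uv >= 0)
  structure(as.list(environment()), class = "morphology_config")
}

#' Render an ECG waveform from ground-truth beat times
#'
#' @param beat_ms beat times (epoch ms), sorted; beats closer than the QRS
#'   width are rejected as nonphysiological.
#' @param fs sampling rate in Hz (typically 500 or 1000).
#' @param morphology a [morphology_config()].
#' @param pad_ms samples rendered before the first / after the last beat
#'   (default 500 ms, enough for a complete QRS-T at the edges).
#' @param seed seed for the noise stream (default 1).
#' @return an [ecg_record()] with `source_label = "synthetic"` whose R-apex
#'   sample coincides with each ground-truth beat time to within half a
#'   sample (noise permitting).
#' @export
synthesize_ecg <- function(beat_ms, fs = 500,
                           morphology = morphology_config(),
                           pad_ms = 500, seed = 1L) {
  stopifnot(fs > 0, length(beat_ms) > 0)
  beat_ms <- as.numeric(beat_ms)
  if (is.unsorted(beat_ms, strictly = TRUE)) stop("beat times must be sorted")
  if (length(beat_ms) > 1L && min(diff(beat_ms)) < morphology$qrs_width_ms) {
    stop("beats closer than the QRS width are nonphysiological")
  }
  period <- 1000 / fs
  t0 <- floor(beat_ms[1L] - pad_ms)
  t1 <- beat_ms[length(beat_ms)] + pad_ms
  n <- as.integer(floor((t1 - t0) / period)) + 1L
  tt <- t0 + (seq_len(n) - 1L) * period
  v <- numeric(n)
  m <- morphology
  pol <- sign(m$rs_ratio)
  amp_r <- m$qrs_amplitude_uv * pol
  amp_s <- -m$qrs_amplitude_uv / abs(m$rs_ratio) * pol
  sig_r <- m$qrs_width_ms / 8
  s_off <- m$qrs_width_ms / 2
  t_off <- 220
  sig_t <- 60
  add_lobe <- function(centre, amp, sig) {
    lo <- max(1L, as.integer(floor((centre - 4 * sig - t0) / period)) + 1L)
    hi <- min(n, as.integer(ceiling((centre + 4 * sig - t0) / period)) + 1L)
    if (hi < lo) return(invisible(NULL))
    idx <- lo:hi
    v[idx] <<- v[idx] + amp * exp(-((tt[idx] - centre)^2) / (2 * sig^2))
    invisible(NULL)
  }
  for (b in beat_ms) {
    add_lobe(b, amp_r, sig_r)
    add_lobe(b + s_off, amp_s, sig_r)
    if (m$t_amplitude_uv != 0) add_lobe(b + t_off, m$t_amplitude_uv * pol,
                                        sig_t)
  }
  if (m$wander_uv > 0) {
    v <- v + m$wander_uv * sin(2 * pi * m$wander_hz * (tt - t0) / 1000)
  }
  if (m$noise_sd_uv > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    v <- v + stats::rnorm(n, 0, m$noise_sd_uv)
  }
  ecg_record(v, fs = fs, start_epoch_ms = t0, source_label = "synthetic")
}

#' Packetise an ECG record as a chest-sensor stream
#'
#' Splits the record into 16-sample packets with relative timestamps and
#' optionally drops packets at random, creating transmission gaps. The
#' result is written/readable through [write_packet_ecg()] /
#' [read_packet_ecg()].
#'
#' @param record an [ecg_record()] (nominally 500 Hz).
#' @param drop_packet_prob per-packet drop probability (default 0).
#' @param seed seed for the drop draw.
#' @return an [ecg_record()] containing only the transmitted samples, with
#'   explicit per-sample times and a `dropouts` table when packets were
#'   dropped; errors if every packet was dropped.
#' @export
simulate_packet_stream <- function(record, drop_packet_prob = 0, seed = 1L) {
  stopifnot(inherits(record, "ecg_record"),
            drop_packet_prob >= 0, drop_packet_prob <= 1)
  n_pkt <- length(record$samples) %/% 16L
  if (n_pkt == 0L) stop("record shorter than one packet")
  keep <- rep(TRUE, n_pkt)
  if (drop_packet_prob > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    keep <- stats::runif(n_pkt) >= drop_packet_prob
  }
  if (!any(keep)) stop("all packets dropped; empty stream")
  tt <- sample_times(record)
  period <- 1000 / record$fs
  pkt_dur <- 16 * period
  sample_idx <- as.vector(vapply(which(keep), function(p) {
    ((p - 1L) * 16L + 1L):(p * 16L)
  }, integer(16L)))
  kept_t <- tt[sample_idx]
  pkt_starts <- tt[(which(keep) - 1L) * 16L + 1L]
  gaps <- diff(pkt_starts)
  gap_idx <- which(gaps > 1.5 * pkt_dur)
  dropouts <- if (length(gap_idx) > 0L) {
    data.frame(start_ms = pkt_starts[gap_idx] + pkt_dur,
               end_ms = pkt_starts[gap_idx + 1L])
  } else NULL
  ecg_record(record$samples[sample_idx], fs = record$fs,
             start_epoch_ms = kept_t[1L],
             source_label = "chest_sensor",
             time_ms = if (is.null(dropouts)) NULL else kept_t,
             dropouts = dropouts)
}

#' RR-device degradation configuration
#'
#' Failure modes of commercial RR-interval chest straps: random per-beat
#' misses (optionally worse above an HR gate, emulating high-intensity
#' dropout), periodic misses (every k-th beat, which halves the apparent
#' heart rate when k = 2), spurious extra beats, Gaussian timing jitter,
#' and no-detection sentinels after long gaps.
#'
#' @param miss_prob per-beat miss probability (default 0).
#' @param miss_prob_high miss probability above `hr_gate_bpm`; `NA` (the
#'   default) disables the intensity-dependent ramp.
#' @param hr_gate_bpm instantaneous-HR gate for `miss_prob_high`
#'   (default 160).
#' @param periodic_miss_k drop every k-th beat (k >= 2); `NA` disables.
#' @param extra_prob per-interval probability of a spurious inserted beat
#'   (default 0).
#' @param jitter_sd_ms Gaussian SD of per-beat timing jitter (default 0).
#' @param sentinel_after_gap_s emit a 5000 ms sentinel code for each full
#'   multiple of this many seconds without a detected beat (default 5);
#'   `NA` disables sentinel emission.
#' @return an object of class `degradation_config`.
#' @export
degradation_config <- function(miss_prob = 0, miss_prob_high = NA,
                               hr_gate_bpm = 160, periodic_miss_k = NA,
                               extra_prob = 0, jitter_sd_ms = 0,
                               sentinel_after_gap_s = 5) {
  stopifnot(miss_prob >= 0, miss_prob <= 1,
            is.na(miss_prob_high) ||
              (miss_prob_high >= 0 && miss_prob_high <= 1),
            is.na(periodic_miss_k) || periodic_miss_k >= 2,
            extra_prob >= 0, extra_prob <= 1, jitter_sd_ms >= 0)
  structure(as.list(environment()), class = "degradation_config")
}

#' Simulate a degraded RR-interval device
#'
#' Applies the configured degradations to ground-truth beat times and
#' recomputes RR' from the surviving events — so a missed beat doubles the
#' local RR', exactly as a real device that missed the beat would report.
#'
#' @param beat_ms ground-truth beat times (epoch ms).
#' @param degradation a [degradation_config()].
#' @param clock_offset_ms constant device clock error added to every
#'   emitted time (default 0).
#' @param seed random seed.
#' @return an [rr_series()] with `source_label = "rr_device"`; the
#'   bookkeeping counts (survivors, missed, extras) are attached as
#'   attribute `"bookkeeping"`.
#' @export
simulate_rr_device <- function(beat_ms, degradation = degradation_config(),
                               clock_offset_ms = 0, seed = 1L) {
  stopifnot(inherits(degradation, "degradation_config"))
  beat_ms <- as.numeric(beat_ms)
  nb <- length(beat_ms)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  d <- degradation
  keep <- rep(TRUE, nb)
  if (!is.na(d$periodic_miss_k)) {
    keep[seq_along(beat_ms) %% d$periodic_miss_k == 0L] <- FALSE
  }
  p_miss <- rep(d$miss_prob, nb)
  if (!is.na(d$miss_prob_high) && nb > 1L) {
    inst_hr <- c(NA, 60000 / diff(beat_ms))
    p_miss[!is.na(inst_hr) & inst_hr >= d$hr_gate_bpm] <- d$miss_prob_high
  }
  keep <- keep & (stats::runif(nb) >= p_miss)
  survivors <- beat_ms[keep]
  n_missed <- nb - length(survivors)
  extras <- numeric(0)
  if (d$extra_prob > 0 && length(survivors) > 1L) {
    gaps <- which(stats::runif(length(survivors) - 1L) < d$extra_prob)
    extras <- (survivors[gaps] + survivors[gaps + 1L]) / 2 +
      stats::rnorm(length(gaps), 0, 10)
  }
  times <- sort(c(survivors, extras))
  if (d$jitter_sd_ms > 0) {
    times <- times + stats::rnorm(length(times), 0, d$jitter_sd_ms)
    times <- sort(times)
  }
  times <- times + clock_offset_ms
  # enforce strict increase (jitter collisions are sub-ms edge cases)
  dup <- which(diff(times) <= 0)
  while (length(dup) > 0L) {
    times[dup + 1L] <- times[dup] + 1
    dup <- which(diff(times) <= 0)
  }
  sentinels <- numeric(0)
  if (!is.na(d$sentinel_after_gap_s) && length(times) > 1L) {
    gap_ms <- d$sentinel_after_gap_s * 1000
    gi <- which(diff(times) >= gap_ms)
    for (g in gi) {
      k <- floor((times[g + 1L] - times[g]) / gap_ms)
      sentinels <- c(sentinels, times[g] + seq_len(k) * gap_ms)
    }
  }
  out <- rr_series(times, sentinel_times_ms = sentinels,
                   source_label = "rr_device")
  attr(out, "bookkeeping") <- list(truth = nb,
                                   survivors = length(survivors),
                                   missed = n_missed,
                                   extras = length(extras))
  out
}

#' Build a complete ground-truthed study fixture
#'
#' Per subject: ground-truth beat times following the protocol profile, a
#' criterion 1000 Hz ECG record, a chest-sensor 500 Hz packet stream, and a
#' degraded RR-device stream, each with its own configurable clock offset,
#' split into the three activity phases. Everything is reproducible under
#' `seed` and the truth is returned alongside the data.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param modes exercise modes cycled across subjects (default
#'   `c("running", "cycling")`).
#' @param seed master seed; per-subject seeds are derived from it.
#' @param profile a [protocol_profile()] (segment durations/HR define the
#'   session; per-subject seeds replace the profile seed).
#' @param morphology a [morphology_config()] for both ECG renderings.
#' @param degradation a [degradation_config()] for the RR device.
#' @param rr_clock_offset_ms clock error injected into the RR device
#'   stream (default 0).
#' @param ecg_clock_offset_ms clock error injected into the chest-sensor
#'   stream (default 0).
#' @param drop_packet_prob chest-sensor packet drop probability (default 0).
#' @return an object of class `study_fixture`: list with `bundles` (a list
#'   of [stream_bundle()]s, one per subject x activity) and `truth` (data
#'   frame `beat_epoch_ms`, `activity`, `subject`, `mode`).
#' @export
make_study_fixture <- function(n_subjects, modes = c("running", "cycling"),
                               seed = 1L,
                               profile = protocol_profile(),
                               morphology = morphology_config(),
                               degradation = degradation_config(),
                               rr_clock_offset_ms = 0,
                               ecg_clock_offset_ms = 0,
                               drop_packet_prob = 0) {
  stopifnot(n_subjects >= 1)
  bundles <- list()
  truth_rows <- list()
  for (s in seq_len(n_subjects)) {
    mode <- modes[(s - 1L) %% length(modes) + 1L]
    sub_seed <- (seed * 1000L + s) %% .Machine$integer.max
    prof <- profile
    prof$seed <- sub_seed
    start_ms <- 1.7e12 + (s - 1L) * 7.2e6  # sessions 2 h apart
    beats <- generate_beat_times(prof, start_epoch_ms = start_ms)
    subject <- sprintf("S%02d", s)
    truth_rows[[s]] <- data.frame(beat_epoch_ms = beats$beat_ms,
                                  activity = beats$activity,
                                  subject = subject, mode = mode)
    for (act in unique(beats$activity)) {
      bt <- beats$beat_ms[beats$activity == act]
      if (length(bt) < 3L) next
      crit <- synthesize_ecg(bt, fs = 1000, morphology = morphology,
                             seed = sub_seed)
      crit$source_label <- "criterion"
      dev <- synthesize_ecg(bt, fs = 500, morphology = morphology,
                            seed = sub_seed + 1L)
      dev <- simulate_packet_stream(dev, drop_packet_prob,
                                    seed = sub_seed + 2L)
      if (ecg_clock_offset_ms != 0) dev <- shift_times(dev,
                                                       ecg_clock_offset_ms)
      rr_dev <- simulate_rr_device(bt, degradation,
                                   clock_offset_ms = rr_clock_offset_ms,
                                   seed = sub_seed + 3L)
      bundles[[length(bundles) + 1L]] <-
        stream_bundle(crit, device_ecg = dev, device_rr = rr_dev,
                      activity_label = act, subject = subject, mode = mode)
    }
  }
  structure(list(bundles = bundles, truth = do.call(rbind, truth_rows)),
            class = "study_fixture")
}

#' @export
print.study_fixture <- function(x, ...) {
  cat(sprintf("Study fixture: %d bundle(s), %d true beats, %d subject(s)\n",
              length(x$bundles), nrow(x$truth),
              length(unique(x$truth$subject))))
  invisible(x)
}

#' Write a study fixture to disk in the three stream dialects
#'
#' One directory per subject x activity containing `criterion.txt`,
#' `chest_sensor.csv`, `rr_device.csv`, plus a pooled `ground_truth.csv`
#' at the top level.
#'
#' @param fixture a `study_fixture` from [make_study_fixture()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "study_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in fixture$bundles) {
    sub <- file.path(dir, sprintf("%s_%s", b$subject, b$activity_label))
    dir.create(sub, showWarnings = FALSE)
    write_criterion_ecg(b$criterion, file.path(sub, "criterion.txt"))
    if (!is.null(b$device_ecg)) {
      write_packet_ecg(b$device_ecg, file.path(sub, "chest_sensor.csv"))
    }
    if (!is.null(b$device_rr)) {
      write_rr_stream(b$device_rr, file.path(sub, "rr_device.csv"))
    }
  }
  utils::write.csv(fixture$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
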