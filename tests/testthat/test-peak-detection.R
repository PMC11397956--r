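# The R-peak detection algorithm: segmentation, per-interval thresholding,
# branch merging, anomaly flagging, local re-search, full pipeline.

test_that("segmentation partitions samples into half-open covering ranges", {
  rec <- ecg_record(rep(0:1, 2500), fs = 500, start_epoch_ms = 1.7e12)
  segs <- segment_intervals(rec, 4)  # 10 s record, 4 s windows
  expect_equal(nrow(segs), 3L)
  expect_equal(segs$end_idx - segs$start_idx + 1L, c(2000L, 2000L, 1000L))
  expect_equal(segs$fs_measured, rep(500, 3), tolerance = 1e-6)

  # interval >= record length -> one range
  segs1 <- segment_intervals(rec, 60)
  expect_equal(nrow(segs1), 1L)
  expect_equal(segs1$start_idx, 1L)
  expect_equal(segs1$end_idx, 5000L)

  # property: union = full index set, pairwise disjoint, random lengths
  set.seed(99)
  for (n in sample(3:5000, 20)) {
    r <- ecg_record(stats::rnorm(n), fs = 500, start_epoch_ms = 0)
    s <- segment_intervals(r, runif(1, 0.5, 8))
    idx <- unlist(mapply(seq, s$start_idx, s$end_idx, SIMPLIFY = FALSE))
    expect_identical(sort(idx), seq_len(n))
    expect_identical(anyDuplicated(idx), 0L)
  }
})

test_that("interval detection finds clean beats at their true times", {
  beats <- steady_beats(n = 10, rr_ms = 1000)
  rec <- synthesize_ecg(beats, fs = 500)
  tt <- sample_times(rec)
  r <- detect_in_interval(rec$samples, tt, "R")
  expect_length(r$idx, 10L)
  expect_true(all(abs(r$time_ms - beats) <= 2))

  # polarity symmetry: negated window under S recovers the same times
  s <- detect_in_interval(-rec$samples, tt, "S")
  expect_equal(s$time_ms, r$time_ms)

  # flat window -> empty
  flat <- detect_in_interval(rep(0, 500), seq(0, 998, by = 2), "R")
  expect_length(flat$idx, 0L)
})

test_that("white-noise-only windows yield at most one spurious candidate", {
  set.seed(7)
  for (i in 1:5) {
    v <- stats::rnorm(5000, 0, 50)
    out <- detect_in_interval(v, seq(0, by = 2, length.out = 5000), "R")
    expect_lte(length(out$idx), 1L)
  }
})

test_that("branch merging collapses duplicates and respects refractory", {
  r <- list(time_ms = c(1000, 2000), amplitude = c(5, 5))
  s <- list(time_ms = c(1005, 3000), amplitude = c(2, 2))
  m <- merge_branches(r, s, refractory_ms = 200)
  expect_equal(m$time_ms, c(1000, 2000, 3000))
  expect_equal(m$branch, c("both", "R", "S"))

  # identical lists -> identity
  m2 <- merge_branches(r, r, refractory_ms = 200)
  expect_equal(m2$time_ms, r$time_ms)
  expect_true(all(m2$branch == "both"))

  # property: random inputs always yield spacing > refractory
  set.seed(31)
  for (i in 1:25) {
    ra <- list(time_ms = sort(runif(20, 0, 10000)),
               amplitude = runif(20, 1, 10))
    sa <- list(time_ms = sort(runif(20, 0, 10000)),
               amplitude = runif(20, 1, 10))
    mm <- merge_branches(ra, sa, refractory_ms = 200)
    if (nrow(mm) > 1L) expect_gt(min(diff(mm$time_ms)), 200)
  }
})

test_that("merge keeps the dominant-lobe time when branches disagree", {
  r <- list(time_ms = 1000, amplitude = 250)   # minor upright lobe
  s <- list(time_ms = 1040, amplitude = 1000)  # dominant inverted lobe
  m <- merge_branches(r, s, refractory_ms = 200)
  expect_equal(m$time_ms, 1040)
  expect_equal(m$branch, "both")
})

test_that("abnormal RR flagging catches gaps but tolerates drift", {
  # steady 800 ms with one doubled gap -> missed-beat flag
  t <- cumsum(c(0, rep(800, 10), 1600, rep(800, 10)))
  fl <- flag_abnormal_rr(t)
  expect_equal(nrow(fl), 1L)
  expect_equal(fl$type, "missed_beat")
  expect_equal(fl$rr_ms, 1600)

  # perfectly steady -> nothing
  expect_equal(nrow(flag_abnormal_rr(cumsum(rep(800, 30)))), 0L)

  # gradual 1000 -> 300 ms ramp over 5 min: tolerated
  rrs <- seq(1000, 300, length.out = 300)
  expect_equal(nrow(flag_abnormal_rr(cumsum(c(0, rrs)))), 0L)

  # fewer than 3 peaks -> warning, empty
  expect_warning(out <- flag_abnormal_rr(c(0, 800)), "fewer than 3")
  expect_equal(nrow(out), 0L)
})

test_that("local re-search recovers a suppressed beat", {
  beats <- steady_beats(n = 10, rr_ms = 1000)
  rec <- synthesize_ecg(beats, fs = 500)
  target <- beats[5]
  found <- local_repeak_search(rec, target, halfwidth_ms = 150,
                               threshold = 800)
  expect_false(is.null(found))
  expect_lte(abs(found$time_ms - target), 2)

  # flat gap -> nothing
  flatrec <- ecg_record(rep(0, 5000), fs = 500,
                        start_epoch_ms = rec$start_epoch_ms)
  expect_null(local_repeak_search(flatrec, rec$start_epoch_ms + 5000,
                                  halfwidth_ms = 150, threshold = 800))

  # window outside record -> NULL with warning
  expect_warning(
    out <- local_repeak_search(rec, rec$start_epoch_ms - 1e6,
                               halfwidth_ms = 100, threshold = 800),
    "outside")
  expect_null(out)
})

test_that("full pipeline detects a clean protocol signal perfectly", {
  beats <- generate_beat_times(short_profile(seed = 42))
  rec <- synthesize_ecg(beats$beat_ms, fs = 500)
  det <- detect_rpeaks(rec)
  m <- match_peaks(beats$beat_ms, det, threshold_ms = 100)
  expect_equal(m$fn, 0L)
  expect_equal(m$fp, 0L)
  expect_equal(sensitivity(m$tp, m$fn), 100)
  expect_equal(precision(m$tp, m$fp), 100)
  # every peak's time is its sample's time exactly
  tt <- sample_times(rec)
  expect_identical(det$peaks$peak_epoch_ms, tt[det$peaks$sample_index])
})

test_that("detection survives noise and baseline wander", {
  beats <- generate_beat_times(short_profile(seed = 42))
  clean <- synthesize_ecg(beats$beat_ms, fs = 500)
  centred <- clean$samples - stats::median(clean$samples)
  rms <- sqrt(mean(centred^2))
  noisy <- synthesize_ecg(
    beats$beat_ms, fs = 500,
    morphology = morphology_config(noise_sd_uv = rms / sqrt(10),  # 10 dB SNR
                                   wander_uv = 0.05 * 1000),
    seed = 7)
  m <- match_peaks(beats$beat_ms, detect_rpeaks(noisy), 100)
  expect_gte(sensitivity(m$tp, m$fn), 99)
})

test_that("inverted-QRS morphology detects at unchanged times", {
  beats <- generate_beat_times(short_profile(seed = 42))
  up <- detect_rpeaks(synthesize_ecg(beats$beat_ms, fs = 500))
  dn <- detect_rpeaks(synthesize_ecg(
    beats$beat_ms, fs = 500,
    morphology = morphology_config(rs_ratio = -4)))
  expect_equal(nrow(up$peaks), nrow(dn$peaks))
  expect_true(all(abs(up$peaks$peak_epoch_ms - dn$peaks$peak_epoch_ms) <= 2))
})

test_that("detection is deterministic and polarity-invariant", {
  beats <- generate_beat_times(short_profile(seed = 8))
  rec <- synthesize_ecg(beats$beat_ms, fs = 500,
                        morphology = morphology_config(noise_sd_uv = 60),
                        seed = 3)
  d1 <- detect_rpeaks(rec)
  d2 <- detect_rpeaks(rec)
  expect_identical(d1$peaks, d2$peaks)

  neg <- rec
  neg$samples <- -neg$samples
  d3 <- detect_rpeaks(neg)
  expect_equal(nrow(d1$peaks), nrow(d3$peaks))
  expect_true(all(abs(d1$peaks$peak_epoch_ms - d3$peaks$peak_epoch_ms) <= 2))
})

test_that("detected peaks respect refractory spacing and sorted order", {
  beats <- generate_beat_times(short_profile(seed = 13))
  rec <- synthesize_ecg(beats$beat_ms, fs = 500,
                        morphology = morphology_config(noise_sd_uv = 80),
                        seed = 5)
  det <- detect_rpeaks(rec)
  pt <- det$peaks$peak_epoch_ms
  expect_false(is.unsorted(pt, strictly = TRUE))
  expect_gt(min(diff(pt)), det$config$refractory_ms)
})

test_that("repair converges: re-detection of a converged result is stable", {
  beats <- generate_beat_times(short_profile(seed = 21))
  rec <- synthesize_ecg(beats$beat_ms, fs = 500)
  det <- detect_rpeaks(rec)
  # a converged clean run makes no repairs
  expect_equal(det$diagnostics$repairs_inserted, 0L)
  expect_equal(det$diagnostics$repairs_removed, 0L)
})

test_that("a flat record yields an empty result with an explanation", {
  flat <- ecg_record(rep(0, 5000), fs = 500, start_epoch_ms = 1.7e12)
  det <- detect_rpeaks(flat)
  expect_equal(nrow(det$peaks), 0L)
  expect_false(det$diagnostics$usable)
  expect_match(det$diagnostics$note, "flat|unusable")
})

test_that("clean detection agrees with an independent energy-based oracle", {
  skip_if_not_installed("signal")
  beats <- generate_beat_times(short_profile(seed = 30))
  rec <- synthesize_ecg(beats$beat_ms, fs = 500)
  ours <- peak_times(detect_rpeaks(rec))
  theirs <- oracle_detect(rec)
  expect_equal(length(ours), length(theirs))
  m <- match_peaks(theirs, ours, threshold_ms = 100)
  expect_equal(m$fn + m$fp, 0L)
  expect_lte(max(abs(m$pairs$dt_ms)), 10)
})
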