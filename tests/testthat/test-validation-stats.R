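# Beat matching, confusion rates, Bland-Altman, ICC(3,1), RR'-SD.

test_that("greedy matching reproduces the brute-force optimum on a toy case", {
  # brute force over all one-to-one pairings of [1000,2000,3000] vs
  # [1040,2950,5000] at 100 ms gives TP=2 (1000-1040, 3000-2950)
  m <- match_peaks(c(1000, 2000, 3000), c(1040, 2950, 5000))
  expect_equal(m$tp, 2L)
  expect_equal(m$fn, 1L)
  expect_equal(m$fp, 1L)
  expect_equal(m$unmatched_criterion_ms, 2000)
  expect_equal(m$unmatched_device_ms, 5000)

  # identical lists
  m2 <- match_peaks(1:10 * 1000, 1:10 * 1000)
  expect_equal(m2$tp, 10L)
  expect_equal(m2$fn + m2$fp, 0L)

  # inclusive boundary at exactly +100 ms
  m3 <- match_peaks(1000, 1100)
  expect_equal(m3$tp, 1L)
  m4 <- match_peaks(1000, 1101)
  expect_equal(m4$tp, 0L)
})

test_that("matching is one-to-one and count-symmetric", {
  set.seed(17)
  for (i in 1:20) {
    a <- sort(runif(40, 0, 40000))
    b <- sort(runif(35, 0, 40000))
    m <- match_peaks(a, b)
    expect_equal(m$tp, nrow(m$pairs))
    expect_equal(m$tp + m$fn, length(a))
    expect_equal(m$tp + m$fp, length(b))
    expect_true(all(abs(m$pairs$dt_ms) <= m$threshold_ms))
    expect_identical(anyDuplicated(m$pairs$dev_idx), 0L)
    # swapping the streams swaps FN and FP, TP unchanged
    ms <- match_peaks(b, a)
    expect_equal(ms$tp, m$tp)
    expect_equal(ms$fn, m$fp)
    expect_equal(ms$fp, m$fn)
  }
})

test_that("raising the matching threshold never loses true positives", {
  set.seed(23)
  a <- sort(runif(100, 0, 1e5))
  b <- a + rnorm(100, 0, 80)
  b <- sort(b)
  tps <- vapply(c(25, 50, 100, 150, 250),
                function(th) match_peaks(a, b, th)$tp, numeric(1))
  expect_true(all(diff(tps) >= 0))
})

test_that("matching is invariant to a global time shift of both streams", {
  set.seed(29)
  a <- sort(runif(50, 0, 5e4))
  b <- sort(a + rnorm(50, 0, 60))
  m0 <- match_peaks(a, b)
  m1 <- match_peaks(a + 123456, b + 123456)
  expect_equal(m1$tp, m0$tp)
  expect_equal(m1$fn, m0$fn)
  expect_equal(m1$fp, m0$fp)
})

test_that("sensitivity and precision reproduce published row values", {
  # values printed in the bundled validation tables
  expect_equal(round(sensitivity(4658, 23), 2), 99.51)
  expect_equal(round(sensitivity(3658, 176), 2), 95.41)
  expect_equal(round(precision(3658, 211), 2), 94.55)
  expect_equal(round(precision(23988, 21), 2), 99.91)
  expect_equal(sensitivity(10, 0), 100)
  expect_equal(precision(10, 0), 100)
  expect_true(is.na(sensitivity(0, 0)))
  expect_true(is.na(precision(0, 0)))
})

test_that("confusion summary reproduces published specificity/accuracy/DER", {
  # chest-strap ECG sensor, all activities pooled
  cs <- confusion_summary(81576, 282, 348,
                          total_samples = 81576 + 282 + 348 + 38059993)
  expect_equal(cs$tn, 38059993)
  expect_equal(round(cs$der, 3), 0.002)
  expect_equal(round(cs$specificity, 3), 99.999)
  expect_equal(round(cs$accuracy, 3), 99.998)

  # RR-interval device, all activities pooled
  g <- confusion_summary(64956, 11634, 9030,
                         total_samples = 64956 + 11634 + 9030 + 37454530)
  expect_equal(round(g$accuracy, 3), 99.945)
  expect_equal(round(g$der, 3), 0.055)

  # degenerate: perfect detector
  p <- confusion_summary(100, 0, 0, total_samples = 10100)
  expect_equal(p$specificity, 100)
  expect_equal(p$accuracy, 100)
  expect_equal(p$der, 0)

  # undefined sensitivity reported as NA, not 0
  u <- confusion_summary(0, 0, 5, total_samples = 1000)
  expect_true(is.na(u$sensitivity))
})

test_that("RR' pairing requires consecutive matched criterion beats", {
  crit <- 1.7e12 + cumsum(c(0, rep(800, 10)))
  # identical streams: all differences zero
  m <- match_peaks(crit, crit)
  d <- paired_rr_differences(m)
  expect_equal(nrow(d), 10L)
  expect_true(all(d$diff_ms == 0))

  # constant 10 ms device delay cancels in the intervals
  m2 <- match_peaks(crit, crit + 10)
  d2 <- paired_rr_differences(m2)
  expect_true(all(abs(d2$diff_ms) < 1e-9))

  # a missed device beat removes the two spanning intervals, not merges
  dev <- crit[-6]
  m3 <- match_peaks(crit, dev)
  d3 <- paired_rr_differences(m3)
  expect_equal(nrow(d3), 8L)  # 10 intervals minus the two touching beat 6
  expect_true(all(abs(d3$diff_ms) < 1e-9))
})

test_that("Bland-Altman statistics match closed forms", {
  ba0 <- bland_altman(c(0, 0, 0))
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$sd_diff, 0)

  ba <- bland_altman(c(-1, 1))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)

  expect_error(bland_altman(5), "at least 2")
})

test_that("RR jitter propagates into difference SD as sigma*sqrt(2)", {
  # Monte-Carlo oracle: differences of intervals built from jittered beat
  # times have SD sigma*sqrt(2)
  set.seed(41)
  sigma <- 20
  truth <- 1.7e12 + cumsum(c(0, rep(800, 2000)))
  dev <- truth + rnorm(length(truth), 0, sigma)
  dev <- sort(dev)
  m <- match_peaks(truth, dev)
  d <- paired_rr_differences(m)
  ba <- bland_altman(d)
  expect_gt(ba$n, 1900)
  expect_lt(abs(ba$sd_diff - sigma * sqrt(2)) / (sigma * sqrt(2)), 0.1)
})

test_that("instantaneous HR converts RR' correctly", {
  expect_equal(instantaneous_hr(1000), 60)
  expect_equal(round(instantaneous_hr(390.3), 1), 153.7)
  expect_equal(round(instantaneous_hr(400.5), 1), 149.8)
  expect_error(instantaneous_hr(0), "positive")
})

test_that("ICC(3,1) matches an independent ANOVA computation", {
  m <- matrix(c(1, 2, 2, 3, 3, 5, 4, 6), ncol = 2, byrow = TRUE)
  # independent oracle: mean squares from stats::aov on the long layout
  long <- data.frame(y = as.vector(m),
                     subj = factor(rep(1:4, 2)),
                     rater = factor(rep(1:2, each = 4)))
  ms <- summary(stats::aov(y ~ subj + rater, data = long))[[1]]$`Mean Sq`
  oracle <- (ms[1] - ms[3]) / (ms[1] + (2 - 1) * ms[3])
  expect_equal(icc3_single(m), oracle, tolerance = 1e-10)
  expect_equal(icc3_single(m), 14 / 15, tolerance = 1e-10)

  # identical columns -> 1; constant column offset -> 1 (consistency form)
  base <- matrix(c(1, 2, 3, 4), ncol = 1)
  expect_equal(icc3_single(cbind(base, base)), 1)
  expect_equal(icc3_single(cbind(base, base + 7)), 1)

  # zero between-subject variance -> NA with warning
  expect_warning(out <- icc3_single(matrix(5, nrow = 3, ncol = 2)),
                 "undefined")
  expect_true(is.na(out))
})

test_that("RR'-SD uses the sample convention and recovers a generator target", {
  expect_equal(rr_sd(c(800, 800, 800)), 0)
  expect_equal(rr_sd(c(700, 900)), sqrt(2 * 100^2), tolerance = 1e-9)

  # resting series generated at SDNN 95 ms recovers the target within 5%
  prof <- protocol_profile(
    data.frame(duration_s = 300, hr_start = 65, hr_end = 65,
               label = "rest_pre", sdnn_ms = 95), seed = 53)
  rr <- rr_series(generate_beat_times(prof)$beat_ms)
  expect_gt(length(rr$rr_ms), 250)
  expect_lt(abs(rr_sd(rr) - 95) / 95, 0.05)
})

test_that("percent-of-mean reproduces published summary percentages", {
  expect_equal(round(percent_of_mean(0.38, 400.5), 2), 0.09)
  expect_equal(round(percent_of_mean(-22.7, 95.54), 2), -23.76)
  expect_equal(percent_of_mean(0, 1234), 0)
  expect_error(percent_of_mean(1, 0), "non-zero")
})

test_that("stratified pooling sums counts before computing rates", {
  tab <- study_table("counts_chest_ecg")
  rep <- stratified_report(tab)
  overall <- rep[rep$activity == "Overall", ]
  expect_equal(round(overall$sensitivity, 2), 99.66)
  expect_equal(round(overall$precision, 2), 99.58)

  # pooled rate bounded by the per-stratum extremes
  strata <- rep[rep$activity != "Overall", ]
  expect_gte(overall$sensitivity, min(strata$sensitivity))
  expect_lte(overall$sensitivity, max(strata$sensitivity))

  # single-stratum input: pooled equals the stratum
  one <- stratified_report(tab[1, ])
  expect_equal(one$sensitivity[1], one$sensitivity[2])

  # empty strata are dropped with a warning
  tab2 <- rbind(tab[1, ],
                data.frame(activity = "incremental", exercise = "rowing",
                           participants = 0, tp = 0, fn = 0,
                           sensitivity_printed = NA, fp = 0,
                           precision_printed = NA))
  expect_warning(stratified_report(tab2), "omitted")
})

test_that("resting-activity pooling reproduces the published combination", {
  rep <- stratified_report(study_table("counts_rr_device"))
  rest <- pool_counts(rep, activities = c("rest_pre", "rest_post"))
  expect_equal(round(rest$sensitivity, 2), 95.83)
  expect_equal(round(rest$precision, 2), 95.88)
})
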