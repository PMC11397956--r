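# Device-validation statistics: beat matching, confusion-derived rates,
# Bland-Altman agreement of RR' intervals, correlation and ICC(3,1).

#' Match device beats to criterion beats
#'
#' Greedy one-to-one nearest-neighbour pairing: walking the criterion peaks
#' in time order, each takes the closest not-yet-consumed device peak within
#' `threshold_ms` (inclusive boundary). Unmatched criterion peaks are false
#' negatives; unmatched device peaks are false positives. One-to-one pairing
#' prevents a single device event from absorbing two criterion beats, which
#' the ~200 ms QRS refractory period rules out physiologically.
#'
#' @param criterion_ms sorted criterion beat times (epoch ms). An
#'   `rpeak_detection` or [rr_series()] may be passed instead.
#' @param device_ms sorted device beat times (likewise coercible).
#' @param threshold_ms matching window in ms (default 100).
#' @return an object of class `match_result`: list with counts `tp`, `fn`,
#'   `fp`, a `pairs` data frame (`crit_idx`, `crit_ms`, `dev_idx`,
#'   `dev_ms`, `dt_ms`), `unmatched_criterion_ms`, `unmatched_device_ms`,
#'   and `threshold_ms`.
#' @export
match_peaks <- function(criterion_ms, device_ms, threshold_ms = 100) {
  as_times <- function(x) {
    if (inherits(x, "rpeak_detection")) return(x$peaks$peak_epoch_ms)
    if (inherits(x, "rr_series")) return(x$beat_epoch_ms)
    as.numeric(x)
  }
  ct <- as_times(criterion_ms)
  dt <- as_times(device_ms)
  stopifnot(!is.unsorted(ct), !is.unsorted(dt), threshold_ms > 0)
  nd <- length(dt)
  consumed <- logical(nd)
  crit_match <- integer(0); dev_match <- integer(0)
  for (i in seq_along(ct)) {
    lo <- findInterval(ct[i] - threshold_ms, dt) + 1L
    hi <- findInterval(ct[i] + threshold_ms, dt)
    if (hi < lo) next
    cand <- lo:hi
    cand <- cand[!consumed[cand]]
    if (length(cand) == 0L) next
    j <- cand[which.min(abs(dt[cand] - ct[i]))]
    if (abs(dt[j] - ct[i]) <= threshold_ms) {
      consumed[j] <- TRUE
      crit_match <- c(crit_match, i)
      dev_match <- c(dev_match, j)
    }
  }
  pairs <- data.frame(crit_idx = crit_match, crit_ms = ct[crit_match],
                      dev_idx = dev_match, dev_ms = dt[dev_match],
                      dt_ms = dt[dev_match] - ct[crit_match])
  structure(
    list(tp = nrow(pairs), fn = length(ct) - nrow(pairs),
         fp = nd - nrow(pairs), pairs = pairs,
         unmatched_criterion_ms = ct[setdiff(seq_along(ct), crit_match)],
         unmatched_device_ms = dt[!consumed],
         threshold_ms = threshold_ms),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("Beat matching @ %g ms: TP %d, FN %d, FP %d\n",
              x$threshold_ms, x$tp, x$fn, x$fp))
  if (x$tp + x$fn > 0) {
    cat(sprintf("  sensitivity %.2f%%", sensitivity(x$tp, x$fn)))
  }
  if (x$tp + x$fp > 0) {
    cat(sprintf("  precision %.2f%%", precision(x$tp, x$fp)))
  }
  cat("\n")
  invisible(x)
}

#' Detection sensitivity (recall)
#'
#' `TP / (TP + FN) * 100`: the percentage of criterion beats the device
#' found.
#'
#' @param tp,fn true positive and false negative counts.
#' @return percentage in `[0, 100]`; `NA` when `tp + fn == 0` (undefined).
#' @export
sensitivity <- function(tp, fn) {
  if (tp + fn == 0) return(NA_real_)
  tp / (tp + fn) * 100
}

#' Detection precision (positive predictive value)
#'
#' `TP / (TP + FP) * 100`: the percentage of device beats that were real.
#'
#' @param tp,fp true positive and false positive counts.
#' @return percentage in `[0, 100]`; `NA` when `tp + fp == 0` (undefined).
#' @export
precision <- function(tp, fp) {
  if (tp + fp == 0) return(NA_real_)
  tp / (tp + fp) * 100
}

#' Confusion summary with sample-level true negatives
#'
#' Event detection on a continuous signal has no natural negative class;
#' the convention here counts every criterion-rate sample not involved in a
#' beat decision as a true negative: `TN = total_samples - TP - FN - FP`.
#' The detection error rate is `DER = (FP + FN) / (TP + TN + FP + FN) * 100`.
#'
#' @param tp,fn,fp beat-level counts (or pass a `match_result` as `tp`).
#' @param total_samples total criterion samples spanning the analysis.
#' @return an object of class `confusion_summary` with counts and the five
#'   rates (percent): `sensitivity`, `precision`, `specificity`,
#'   `accuracy`, `der`. Undefined rates are `NA`, not 0.
#' @export
confusion_summary <- function(tp, fn = NULL, fp = NULL, total_samples) {
  if (inherits(tp, "match_result")) {
    m <- tp; tp <- m$tp; fn <- m$fn; fp <- m$fp
  }
  stopifnot(tp >= 0, fn >= 0, fp >= 0,
            total_samples >= tp + fn + fp)
  tn <- total_samples - tp - fn - fp
  total <- tp + tn + fp + fn
  structure(
    list(tp = tp, fn = fn, fp = fp, tn = tn,
         sensitivity = sensitivity(tp, fn),
         precision = precision(tp, fp),
         specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp) * 100,
         accuracy = if (total == 0) NA_real_ else (tp + tn) / total * 100,
         der = if (total == 0) NA_real_ else (fp + fn) / total * 100),
    class = "confusion_summary"
  )
}

#' @export
print.confusion_summary <- function(x, digits = 3, ...) {
  cat(sprintf("TP %d  FN %d  FP %d  TN %.0f\n", x$tp, x$fn, x$fp, x$tn))
  cat(sprintf(
    "sensitivity %.*f%%  precision %.*f%%  specificity %.*f%%  accuracy %.*f%%  DER %.*f%%\n",
    digits, x$sensitivity, digits, x$precision, digits, x$specificity,
    digits, x$accuracy, digits, x$der))
  invisible(x)
}

#' Paired RR' differences for Bland-Altman analysis
#'
#' An RR' pair exists only where two consecutive criterion beats are both
#' matched: the difference is the device's inter-partner interval minus the
#' criterion RR', paired with the two-device mean. Intervals spanning a
#' missed beat are excluded rather than compared against a summed interval,
#' keeping the differences interpretable.
#'
#' @param match a `match_result` from [match_peaks()].
#' @return data frame with columns `mean_rr_ms` and `diff_ms`
#'   (device - criterion); zero rows when fewer than 2 usable pairs exist.
#' @export
paired_rr_differences <- function(match) {
  stopifnot(inherits(match, "match_result"))
  p <- match$pairs
  empty <- data.frame(mean_rr_ms = numeric(0), diff_ms = numeric(0))
  if (nrow(p) < 2L) return(empty)
  p <- p[order(p$crit_idx), , drop = FALSE]
  consec <- which(diff(p$crit_idx) == 1L)
  if (length(consec) == 0L) return(empty)
  crit_rr <- p$crit_ms[consec + 1L] - p$crit_ms[consec]
  dev_rr <- p$dev_ms[consec + 1L] - p$dev_ms[consec]
  ok <- dev_rr > 0
  data.frame(mean_rr_ms = (crit_rr[ok] + dev_rr[ok]) / 2,
             diff_ms = dev_rr[ok] - crit_rr[ok])
}

#' Bland-Altman agreement statistics
#'
#' Mean and sample standard deviation (n - 1) of paired differences, with
#' limits of agreement at `mean +/- 1.96 * SD`.
#'
#' @param diffs numeric vector of differences, or the data frame returned
#'   by [paired_rr_differences()] (its `diff_ms`/`mean_rr_ms` columns are
#'   used, enabling the plot method).
#' @return an object of class `bland_altman`: `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(diffs) {
  means <- NULL
  if (is.data.frame(diffs)) {
    means <- diffs$mean_rr_ms
    diffs <- diffs$diff_ms
  }
  if (length(diffs) < 2L) stop("need at least 2 differences")
  m <- mean(diffs)
  s <- stats::sd(diffs)
  structure(
    list(mean_diff = m, sd_diff = s,
         loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
         n = length(diffs), diffs = diffs, means = means),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): mean %.2f ms (SD %.2f), LoA [%.2f, %.2f] ms\n",
    x$n, x$mean_diff, x$sd_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, alpha = 0.3, ...) {
  if (is.null(x$means)) stop("no pair means stored; nothing to plot")
  col <- grDevices::adjustcolor("steelblue", alpha.f = alpha)
  graphics::plot(x$means, x$diffs, pch = 20, col = col,
                 xlab = "mean RR' (ms)",
                 ylab = "difference, device - criterion (ms)", ...)
  graphics::abline(h = c(x$loa_low, x$mean_diff, x$loa_high),
                   lty = c(2, 1, 2), col = "gray30")
  invisible(x)
}

#' Instantaneous heart rate from an RR' interval
#' @param rr_ms RR' interval(s) in ms (> 0).
#' @return heart rate in beats per minute, `60000 / rr_ms`.
#' @export
instantaneous_hr <- function(rr_ms) {
  if (any(rr_ms <= 0)) stop("RR' intervals must be positive")
  60000 / rr_ms
}

#' Intraclass correlation ICC(3,1)
#'
#' Two-way mixed model, single measure, consistency form:
#' `(MS_rows - MS_error) / (MS_rows + (k - 1) * MS_error)`, with raters
#' (devices) as fixed effects. The consistency form ignores a constant
#' offset between columns, matching the fixed-rater reading of device
#' comparison.
#'
#' @param ratings numeric matrix or data frame, subjects in rows, the two
#'   (or more) devices in columns; no missing cells.
#' @return the ICC(3,1) coefficient in `[-1, 1]`; `NA` with a warning when
#'   the between-subject variance is zero (undefined).
#' @export
icc3_single <- function(ratings) {
  m <- as.matrix(ratings)
  if (anyNA(m)) stop("ratings must have no missing cells")
  n <- nrow(m); k <- ncol(m)
  if (n < 3L || k < 2L) stop("need >= 3 subjects and >= 2 raters")
  gm <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - gm)^2)
  ss_cols <- n * sum((col_m - gm)^2)
  ss_tot <- sum((m - gm)^2)
  ms_rows <- ss_rows / (n - 1)
  ms_err <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  if (ms_rows == 0 && ms_err == 0) {
    warning("zero between-subject variance; ICC undefined")
    return(NA_real_)
  }
  (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
}

#' Standard deviation of an RR' interval series
#'
#' Sample SD (n - 1) of the RR' intervals — the time-domain HRV measure
#' used for resting comparisons (SDNN when computed over normal beats).
#'
#' @param rr_ms RR' intervals in ms, or an [rr_series()].
#' @return SD in ms.
#' @export
rr_sd <- function(rr_ms) {
  if (inherits(rr_ms, "rr_series")) rr_ms <- rr_ms$rr_ms
  if (length(rr_ms) < 2L) stop("need at least 2 intervals")
  stats::sd(rr_ms)
}

#' Mean difference as a percentage of a reference mean
#' @param mean_diff mean paired difference (ms).
#' @param reference_mean reference mean (ms, non-zero).
#' @return `mean_diff / reference_mean * 100`.
#' @export
percent_of_mean <- function(mean_diff, reference_mean) {
  if (any(reference_mean == 0)) stop("reference mean must be non-zero")
  mean_diff / reference_mean * 100
}

#' Stratified sensitivity/precision report
#'
#' Builds the per-stratum table of a device validation: one row per
#' activity-by-exercise stratum with summed counts and the derived rates,
#' plus a pooled row. Pooling sums the counts and then computes the rates —
#' never a mean of per-stratum rates.
#'
#' @param counts data frame with columns `activity`, `exercise`, `tp`,
#'   `fn`, `fp` (one or more rows per stratum; extra columns such as
#'   `participants` are summed too when numeric). A list of
#'   `match_result` objects with parallel `activity`/`exercise` label
#'   vectors may be given instead via `matches`, `activity`, `exercise`.
#' @param matches optional list of `match_result` objects.
#' @param activity,exercise label vectors parallel to `matches`.
#' @return an object of class `stratified_report`: data frame with columns
#'   `activity`, `exercise`, `tp`, `fn`, `sensitivity`, `fp`, `precision`;
#'   the final row pools all strata (`activity = "Overall"`). Empty strata
#'   are omitted with a warning.
#' @export
stratified_report <- function(counts = NULL, matches = NULL,
                              activity = NULL, exercise = NULL) {
  if (is.null(counts)) {
    stopifnot(!is.null(matches), length(matches) == length(activity),
              length(matches) == length(exercise))
    counts <- do.call(rbind, lapply(seq_along(matches), function(i) {
      m <- matches[[i]]
      data.frame(activity = activity[i], exercise = exercise[i],
                 tp = m$tp, fn = m$fn, fp = m$fp)
    }))
  }
  stopifnot(all(c("activity", "exercise", "tp", "fn", "fp") %in%
                  names(counts)))
  empty <- counts$tp + counts$fn + counts$fp == 0
  if (any(empty)) {
    warning(sprintf("%d empty stratum/strata omitted", sum(empty)))
    counts <- counts[!empty, , drop = FALSE]
  }
  key <- interaction(counts$activity, counts$exercise, drop = TRUE)
  agg <- do.call(rbind, lapply(split(counts, key), function(d) {
    data.frame(activity = d$activity[1L], exercise = d$exercise[1L],
               tp = sum(d$tp), fn = sum(d$fn), fp = sum(d$fp))
  }))
  agg <- agg[order(agg$activity, agg$exercise), , drop = FALSE]
  pooled <- data.frame(activity = "Overall", exercise = "All",
                       tp = sum(agg$tp), fn = sum(agg$fn),
                       fp = sum(agg$fp))
  out <- rbind(agg, pooled)
  out$sensitivity <- mapply(sensitivity, out$tp, out$fn)
  out$precision <- mapply(precision, out$tp, out$fp)
  out <- out[c("activity", "exercise", "tp", "fn", "sensitivity",
               "fp", "precision")]
  rownames(out) <- NULL
  class(out) <- c("stratified_report", "data.frame")
  out
}

#' @export
print.stratified_report <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  y$sensitivity <- sprintf("%.*f%%", digits, y$sensitivity)
  y$precision <- sprintf("%.*f%%", digits, y$precision)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Pooled counts of a stratified report
#'
#' @param report a `stratified_report`.
#' @param activities optional subset of activity labels to pool (rates are
#'   recomputed from the summed counts).
#' @return one-row data frame with pooled `tp`, `fn`, `fp`, `sensitivity`,
#'   `precision`.
#' @export
pool_counts <- function(report, activities = NULL) {
  d <- as.data.frame(report)
  d <- d[d$activity != "Overall", , drop = FALSE]
  if (!is.null(activities)) d <- d[d$activity %in% activities, , drop = FALSE]
  data.frame(tp = sum(d$tp), fn = sum(d$fn), fp = sum(d$fp),
             sensitivity = sensitivity(sum(d$tp), sum(d$fn)),
             precision = precision(sum(d$tp), sum(d$fp)))
}
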