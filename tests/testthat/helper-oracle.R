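# Independent QRS-detector oracle for cross-checking detect_rpeaks() on
# clean signals. Classic derivative/energy pipeline (band-pass, square,
# moving-window integration, fixed-fraction threshold) — deliberately a
# different algorithm family from the package's voltage-sorted threshold
# search, and used only in tests.

oracle_detect <- function(record) {
  fs <- record$fs
  v <- record$samples - stats::median(record$samples)
  bp <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  f <- signal::filtfilt(bp, v)
  energy <- f^2
  w <- max(1L, as.integer(round(0.15 * fs)))
  integ <- stats::filter(energy, rep(1 / w, w), sides = 2)
  integ[is.na(integ)] <- 0
  thr <- 0.2 * max(integ)
  above <- integ > thr
  # rising edges of supra-threshold bursts
  starts <- which(diff(c(FALSE, above)) == 1)
  ends <- which(diff(c(above, FALSE)) == -1)
  tt <- sample_times(record)
  peaks <- numeric(0)
  half <- as.integer(round(0.1 * fs))
  for (k in seq_along(starts)) {
    lo <- max(1L, starts[k] - half)
    hi <- min(length(v), ends[k] + half)
    idx <- lo:hi
    apex <- idx[which.max(abs(v[idx]))]
    if (length(peaks) == 0L ||
        tt[apex] - peaks[length(peaks)] > 200) {
      peaks <- c(peaks, tt[apex])
    }
  }
  peaks
}
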