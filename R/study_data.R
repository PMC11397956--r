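#' Bundled published validation tables
#'
#' Summary tables from a published validation of two heart-rate wearables
#' (a chest-strap single-channel ECG sensor and a commercial RR-interval
#' chest strap) against a three-lead laboratory ECG, bundled as plain CSV
#' under `inst/extdata`. They are inputs to the worked examples and the
#' acceptance script: the package recomputes every derived rate from the
#' raw counts.
#'
#' Available tables:
#' * `"counts_chest_ecg"`, `"counts_rr_device"` — per activity x exercise
#'   beat-matching counts (TP, FN, FP) with the printed sensitivity and
#'   precision percentages for cross-checking.
#' * `"activity_summary"` — per-stratum mean RR', HR, max HR and RR'-SD.
#' * `"agreement_summary"` — published Bland-Altman mean differences with
#'   their reference means and printed percent-of-mean values. (The
#'   RR-device resting row reproduces the source's printed percentage,
#'   whose sign is inconsistent with its printed mean difference; both are
#'   kept as printed.)
#' * `"confusion_totals"` — published sample-level TN totals with printed
#'   DER/specificity/accuracy.
#'
#' @param table one of the names above.
#' @return a data frame.
#' @export
study_table <- function(table = c("counts_chest_ecg", "counts_rr_device",
                                  "activity_summary", "agreement_summary",
                                  "confusion_totals")) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0(table, ".csv"),
                      package = "ecgvalidate", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
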