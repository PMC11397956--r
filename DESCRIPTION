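Package: ecgvalidate
Title: R-Peak Detection and Validation of Wearable ECG Heart-Rate Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for validating heart-rate wearables against a criterion
    electrocardiogram. Provides readers and writers for three device stream
    dialects (plain-text criterion ECG, packetised chest-sensor ECG, and
    RR-interval exports with FIT-epoch timestamps), an exercise-robust
    R-peak detection algorithm based on interval-wise voltage-sorted
    thresholding with dual upright/inverted passes and statistical repair of
    abnormal RR intervals, tachogram cross-correlation synchronisation of
    multi-device streams, and a beat-matching validation suite (sensitivity,
    precision, detection error rate, Bland-Altman limits of agreement,
    Pearson correlation and ICC(3,1)). A ground-truthed synthetic ECG
    generator emulates rest/incremental-exercise/recovery protocols and the
    failure modes of commercial RR-interval devices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    signal,
    withr
Config/testthat/edition: 3
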