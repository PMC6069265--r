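Package: wristgait
Title: Step Detection and Walking Distance Estimation from Wrist-Worn
    Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hierarchical walking-distance estimation from tri-axial
    wrist accelerometer traces. Implements two-stage support-vector-machine
    activity recognition for five wrist activities during walking (texting,
    calling, hand in pocket, suitcase carrying, arm swinging), robust step
    detection with adaptive peak/valley thresholds, abnormal-interval
    minimum correction, misclassification feedback and maximum correction,
    and non-parametric step-length estimation in which the per-step
    K-factor of the Weinberg, Kim and Tian equations is modelled by locally
    weighted polynomial regression on the per-step mean-velocity magnitude.
    Includes a synthetic gait-signal generator with exact ground truth and
    a leave-one-sample-out evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
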