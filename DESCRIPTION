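Package: stairgait
Title: Wearable-Sensor and Neural-Network Estimation of Hip Biomechanics
    During Stair Ascent
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale workflow for estimating sagittal- and frontal-plane
    hip joint angles and mass-normalized moments during stair ascent from two
    inertial measurement units (shank, thigh) and one force-instrumented
    insole. Provides delimited-text sensor stream input/output with standard
    gait pre-processing (zero-phase Butterworth filtering, resampling,
    shank-sensor axis re-alignment), per-modality gait-event detection and
    temporal synchronization, a planar link-segment inverse-dynamics
    surrogate of the laboratory gold standard, a calibrated synthetic
    stair-ascent cohort generator with virtual sensors, a compact two-hidden-
    layer feed-forward network trained by Levenberg-Marquardt with
    Nguyen-Widrow initialization, and a subject-wise leave-one-out
    cross-validation harness reporting relative root-mean-square error and
    coefficients of determination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
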