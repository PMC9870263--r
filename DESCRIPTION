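Package: imugait
Title: Hip and Knee Flexion Angles from Three Body-Worn Orientation Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes sagittal-plane hip and knee flexion angles during gait
    from the longitudinal-axis ("roll") rotation of three inertial
    measurement units worn on the sacrum, thigh and shank, using a
    single-axis rotation model (knee = thigh roll - shank roll,
    hip = sacrum roll - thigh roll). Includes static-trial zeroing
    calibration, cross-correlation time alignment against a camera-based
    reference stream, and a method-agreement validation battery
    (Bland-Altman bias and 95 percent limits of agreement, repeatability
    coefficient, per-participant linear regression, MAE, RMSE, and paired
    before/after-session comparisons). A synthetic gait-session simulator
    with sensor-noise models (mounting offsets, drift, soft-tissue
    artifact, attachment degradation) exercises the full pipeline without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
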