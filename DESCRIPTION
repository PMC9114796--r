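Package: gaitpath
Title: Stride-Level Foot-Trajectory Estimation and Spatial Gait Features from Shank-Worn IMUs
Version: 0.1.0
Authors@R:
    person("gaitpath", "developers", email = "gaitpath@example.org", role = c("aut", "cre"))
Description: Estimates stride-by-stride 3-D foot (ankle-point) trajectories from
    shank-mounted inertial measurement units by gravity-anchored strapdown
    integration with forward/backward drift-cancelling integration, extracts six
    spatial gait features (forward and vertical displacements at toe-off, maximum
    clearance, and change of supporting leg), and provides the group-level
    statistical toolchain used in movement-disorder gait phenotyping: one-way
    ANOVA with Shaffer sequentially rejective post hoc tests, principal component
    analysis with Horn-style parallel analysis, and soft-margin kernel SVM
    discrimination with stratified cross-validation. A ground-truthed synthetic
    gait generator renders world-frame ankle kinematics into sensor-frame IMU
    signals so that the full pipeline is testable without access to clinical
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
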