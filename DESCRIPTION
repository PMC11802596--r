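Package: kinetap
Title: Kinematic Motor Signatures from Smart-Tablet Gameplay
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for touch-screen and inertial (IMU) recordings
    of free tablet gameplay in children. Segments raw touch streams into
    atomic gestures, derives per-gesture kinematics (speed, tangential
    acceleration, convex-hull area, directness), builds a frozen 269-feature
    session representation (105 touch, 164 IMU) and per-movement
    time-normalized bin profiles, trains class-weighted shallow neural
    networks and gradient-boosted trees with subject-level leave-one-out and
    repeated/nested k-fold cross-validation, and screens features with
    normality-gated nonparametric group tests and Kendall correlations. A
    deterministic synthetic-gameplay generator emulates cohorts of
    typically-developing, autistic and developmental-coordination-disorder
    children so every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    nortest,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
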