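Package: handkin
Title: Markerless Hand Kinematics Validation Against Marker-Based Motion
    Capture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Infers two-dimensional finger joint kinematics from
    single-camera hand keypoint streams and validates them against
    projected three-dimensional marker-based kinematics.  Provides readers
    for per-frame hand keypoint JSON and marker trajectory tables, Hampel
    outlier filtering and zero-phase Butterworth smoothing with
    residual-analysis cutoff selection, per-activity joint-angle catalogs,
    Total Active Flexion extraction, method-agreement statistics (RMSE,
    Bland-Altman limits of agreement, linear regression), and an
    articulated planar-hand simulator that generates ground-truth fixtures
    for end-to-end validation runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    zoo
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
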