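Package: tagtrax
Title: Post-Processing and Tag-Effect Analysis for Animal Pose-Tracking Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns multi-landmark pose-tracking tables (DeepLabCut-style CSV)
    into calibrated centroid trajectories and three locomotor traits (average
    speed, walk-bout count, zone exploration), and compares tagged versus
    untagged groups of animals with a transformation-aware linear-model
    procedure (Shapiro-Wilk residual check, Type II F tests). Includes a
    correlated-random-walk simulator of open-field trials with stop/walk bout
    structure, wall-following bias and landmark-level observation noise, so
    the full chain can be validated by parameter recovery without raw videos.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    car,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
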