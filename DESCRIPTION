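Package: FishMOT
Title: Cascade Multi-Fish Tracking and Multi-Object Tracking Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tracking-by-detection for dense fish schools recorded in
    aquaculture tanks. Links per-frame detector boxes into identity-bearing
    trajectories with a constant-velocity Kalman filter and a three-stage
    cascade association (Mahalanobis gating, IoU overlap, centroid distance)
    solved by the Hungarian algorithm, with score-decayed coasting and
    age-based track purging. Includes the occlusion-aware focal/Dice loss
    arithmetic with sign-driven adaptive weighting, a complete multi-object
    tracking evaluation suite (MOTA, MOTP, IDF1/IDP/IDR, MT/ML, HOTA with
    DetA/AssA), MOTChallenge CSV readers and writers, and a seeded
    fish-school simulator that generates ground truth and corrupted
    detection streams (occlusion, deformation, dropout, clutter) emulating
    high-density tank recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
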