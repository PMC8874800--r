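Package: vrmotion
Title: Kinematic Analysis and Classification of Bimanual Movements from
    Virtual-Reality Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing coordinated bimanual upper-limb movements
    recorded by consumer virtual-reality hardware (a head-mounted display and
    two hand-held controllers). Raw 6-DoF pose time series are converted to
    controller poses relative to the head frame via homogeneous transforms,
    movement repetitions are segmented from a combined-controller speed
    statistic, salient kinematic variables are selected per segment by a
    spectral-gap rule on the covariance eigenspectrum, and sliding-window
    feature vectors are classified with a bagged decision-tree ensemble with
    out-of-bag permutation importance. Includes per-user range-of-motion
    calibration with cursor-threshold derivation, four motor-performance
    metrics (range of motion, mean speed, smoothness, path length), and a
    synthetic calibration-session generator with minimum-jerk trajectories
    for validation without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
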