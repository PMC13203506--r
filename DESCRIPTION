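Package: duotrack
Title: Dual-Locking Multi-Object Tracking for Livestock Video Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Maintains stable identities of group-housed animals in overhead
    video with a dual-locking tracker: a primary locker combining an
    eight-dimensional constant-velocity Kalman filter with appearance
    re-identification and a tiered matching cascade, and an auxiliary
    kernelized correlation filter (KCF) locker over HOG features that keeps
    providing position estimates through detector dropouts. Overlapping
    lockers are arbitrated by a multi-criteria conflict-coverage score
    (detection confidence, historical stability, trajectory maturity).
    Includes CLEAR-MOT and IDF1 evaluation with locking-duration statistics,
    a synthetic pen-scene generator with an occlusion-driven detection-noise
    emulator, detector loss formulas (binary cross-entropy, complete-IoU,
    weighted composite), letterbox and adaptive-resize preprocessing, and a
    pure-software model of a pan-tilt gimbal serial control protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
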