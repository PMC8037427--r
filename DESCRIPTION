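Package: footreg
Title: Registration and Evaluation of Thermal Infrared and Visible Foot Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for registering thermal-infrared and visible-spectrum images
    of feet acquired by a fixed two-camera rig, as used in remote monitoring of
    the diabetic foot. Implements four planar registration estimators (geometric
    optical translation, RANSAC homography, rigid iterative closest point on
    mask contours, and affine registration by adaptive stochastic gradient
    descent), STAPLE expectation-maximisation fusion of multi-rater
    segmentations, segmentation overlap metrics (Dice, Jaccard, volume
    similarity, false-negative and false-positive fractions), frame-stream
    synchronization, and a synthetic two-camera scene generator with known
    ground-truth transforms for end-to-end benchmarking, including a
    working-distance robustness experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
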