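Package: scolioscreen
Title: Radiation-Free Scoliosis Screening from Back Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Geometry-based evaluation of scoliosis from back photographs.
    Fits a quartic spine curve to labeled back keypoints, classifies the
    coronal curvature as C-, S- or multi-curved, grades severity via a fused
    Cobb-angle / scapular-triangle rule, and measures the sagittal angle of
    trunk rotation (ATR) from bent-forward silhouettes using classical edge
    detection and automatic multiscale peak detection (AMPD). Ships
    ground-truthed synthetic generators for every pipeline stage and the
    evaluation metrics (accuracy, precision, recall, F1, Cohen's kappa,
    object keypoint similarity, mean relative error) needed to score the
    pipeline against labeled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
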