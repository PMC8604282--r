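Package: weedspot
Title: Multi-Modal RGB-D Weed Detection in Wheat Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for detecting grass and broad-leaf weeds in top-down
    RGB-D imagery of wheat fields. Recodes single-channel depth rasters into
    three-channel PHA images (phase, height above ground, angle with
    gravity), aligns depth to the colour camera through a two-sensor pinhole
    model, fills depth holes, and runs a three-branch multiscale detection
    network (RGB-specific, PHA-specific, and cross-modal Hadamard-fused
    branches with region proposal networks) trained by stochastic gradient
    descent. Branch detections are combined by decision-level weighted
    ensembling with a grid search over the simplex of branch weights, and
    evaluated by per-class average precision, mAP and intersection over
    ground truth (IoG). A seedable synthetic wheat-field scene generator
    with Pascal VOC annotations makes the full pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
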