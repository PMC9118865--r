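Package: stalkscan
Title: Plant Counting and Pseudo-Stem Morphometry from Terrestrial Laser Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Counts banana plants and measures pseudo-stem diameter and height
    from terrestrial laser scanning (TLS) point clouds of closed-canopy
    plantations. Provides PCD/LAS point-cloud input, voxel downsampling,
    statistical outlier removal, RANSAC ground-plane segmentation, fixed-height
    band extraction with Euclidean clustering and bounding-box classification of
    pseudo-stems versus bamboo poles and broken leaves, seeded K-means single
    plant segmentation, moving-least-squares smoothing with RANSAC cylinder
    fitting for stem diameter, sliding-window detection of the leaf/pseudo-stem
    junction for stem height, counting and regression evaluation metrics, and a
    parametric synthetic banana-field generator with exact ground truth for
    end-to-end verification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    withr,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
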