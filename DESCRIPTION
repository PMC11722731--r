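Package: streetseg
Title: Hierarchical Segmentation and Morphometry of Street Trees from
    Mobile Laser Scanning Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Individual-tree segmentation of roadside mobile-laser-scanning
    (MLS) point clouds by density-based pre-segmentation (DBSCAN), a
    topology-checking merge of over-segmented crown fragments via XOY
    footprint overlay, trunk-skeleton removal of pole-like interference, and
    a density-valley voxel split of under-segmented multi-tree clusters
    anchored on breast-height circle fits. Per-tree morphometry (height,
    diameter at breast height by least-squares circle fitting, convex-hull
    crown diameter and crown area), point- and tree-oriented evaluation
    metrics (precision, recall, F1, crown-area IoU), and a seeded synthetic
    street-scene generator for end-to-end testing. Point clouds and tree
    records are tibbles throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
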