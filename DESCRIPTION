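Package: helaxis
Title: Finite Helical Axis Analysis of Serial 3D Surface Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the three-dimensional movement of individual rigid
    anatomical structures (such as tooth crowns on serial dental cast scans)
    between timepoints. Serial point clouds are registered to a common
    coordinate frame on a stable reference structure, a rotation matrix and
    translation vector are estimated per structure per interval by iterative
    closest point registration with an SVD least-squares inner fit, and each
    rigid transform is decomposed into its finite helical (screw) axis:
    axis direction, a point on the axis, rotation angle about the axis and
    translation along it. Includes the mean-fitting-error registration
    quality metric, a total-least-squares calibration-plane check, a
    deterministic synthetic scan-series generator with known screw-motion
    ground truth, and readers/writers for PLY, OBJ and XYZ point clouds.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
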