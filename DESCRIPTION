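Package: contourflow
Title: Regularized Contour Flows for Amoeboid Cell-Shape Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Smooth periodic representations of segmented cell outlines via
    Gaussian-process regression with a Poisson kernel, a one-parameter family
    of regularized virtual-marker flows between successive contours,
    kymographs of local dispersion, local motion and curvature in a strongly
    regularized boundary coordinate system, and automated detection and
    statistics of membrane expansions and contractions. Includes a synthetic
    contour-track generator with analytically known deformation fields so
    that every pipeline stage can be validated against closed-form ground
    truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
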