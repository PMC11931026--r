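Package: orbitnerf
Title: Metric 3D Plant Reconstruction from Orbital Multi-View Video with
    ROI-Constrained Neural Radiance Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing metric 3D models of individual plants
    from videos captured by a camera orbiting the plant on two horizontal
    rings of known radius and heights.  The pipeline selects sharp keyframes
    by Laplacian-variance scoring, calibrates structure-from-motion camera
    poses to metric world coordinates using the circular imaging trajectory
    as a prior, trains a region-of-interest constrained neural radiance
    field with multi-resolution hash encoding, shallow perceptrons,
    learnable per-image exposure and camera-pose refinement, and extracts a
    metric surface mesh from which phenotypes such as plant height are
    measured.  A deterministic synthetic-scene generator with a quadrature
    reference renderer makes every stage testable without captured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    png,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
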