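Package: thalagrad
Title: Thalamocortical Connectivity Gradients from Streamline Endpoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds dense thalamic-seed by cortical-vertex structural
    connectomes from tractography streamline endpoints (nearest-vertex
    assignment, fractional-anisotropy weighting, surface-based Gaussian
    smoothing, low-connectivity seed filtering, scaled-sigmoid
    normalization), extracts principal connectivity gradients by singular
    value decomposition, aligns individual decompositions to a group
    template with an orthogonal Procrustes rotation, and provides the
    accompanying spatial statistics: spin-test spatial null models,
    FDR-corrected age-correlation maps, Cartesian-axis correlations, and
    permutation inference on the general linear model with threshold-free
    cluster enhancement. A synthetic-cohort generator with planted
    low-rank gradients provides a ground-truth surface for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
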