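Package: datascaper
Title: Shape-Aware Abstraction of Point Clouds via Neighborhood Graphs and Local Convex Hulls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Abstracts a numeric point cloud as a symmetrized k-nearest-neighbor
    graph combined with the union of per-point neighborhood convex hulls (the
    "datascape"). The resulting object supports geodesic distances that follow
    the shape of the data, identification of boundary (extreme) points,
    inside/outside membership queries for new points, rejection-free sampling
    inside the estimated shape, and neighborhood label-ratio risk scoring with
    out-of-sample prediction. Includes generators for benchmark manifolds
    (noisy sinusoid, torus, unit circle, labeled two-class cohorts) and the
    associated distance-error and topology-scan experiments, plus a small
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
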