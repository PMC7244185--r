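Package: oncostream
Title: Agent-Based Simulation of Collective Migration of Elongated Glioma Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the collective motion of self-propelled, ellipse- or
    ellipsoid-shaped cells in a periodic box. Anisotropic excluded-volume
    repulsion and tension-reducing steering produce indirect alignment and,
    depending on repulsion strength, steering strength and density, flocking,
    bidirectional streaming (the histological "oncostream" pattern seen in
    gliomas) or scattered states. Provides the exact right-hand side of the
    equations of motion with analytic gradients, an explicit Euler integrator
    with cell-list neighbor search, polar and nematic order parameters,
    size-weighted cluster statistics, a closed-form two-cell steering oracle,
    and (alpha, beta) phase-diagram sweeps with loess smoothing and region
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    ggplot2,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
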