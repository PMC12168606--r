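Package: cryostruct
Title: Structure Refinement and Water-Cluster Analysis of Glycerol-Water
    Cryoprotectant Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Atomistic Monte Carlo modelling of glycerol-water mixtures
    against X-ray total-scattering data. Implements semi-rigid-molecule
    Metropolis Monte Carlo with Lennard-Jones, Coulomb and empirical
    (data-driven) pair potentials, conversion between ensembles, partial
    pair distribution functions g(r), X-ray weighted structure factors
    S(Q) and the real-space functions G(r) and T(r), composition
    calibration of unknown patterns from intramolecular peak-height
    ratios, and water-cluster percolation analysis that locates the
    dehydration threshold below which ice-nucleating water clusters
    cannot form. Ships a synthetic-data generator emulating glycerol-water
    standards and chitin-contaminated larval patterns so the whole
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
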