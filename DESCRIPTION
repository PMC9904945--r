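Package: geomconflict
Title: Two-Optima Geometric Model of Adaptation Under Evolutionary Conflict
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulator and analysis toolkit for a two-party extension of
    Fisher's geometric model of adaptation, in which two agents with distinct
    phenotypic optima (or pessima) each govern a share of incoming mutations.
    Provides the origin-fixation invasion dynamics over a bounded phenotype
    space with fully pleiotropic or fully modular mutation, exact
    one-dimensional interval kernels and general Monte Carlo estimators for
    the intensity of evolutionary conflict, long-run maladaptation and
    occupancy summaries with block-bootstrap errors, power-law scaling fits
    for the conflict-driven cost of complexity, scripted experiment drivers
    (equilibrium dynamics, dimensionality sweeps, modularity, balance of
    power, pessimum avoidance, compromise accounting), and CSV/JSON
    serialization with a reproducible run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
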