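Package: bridgesim
Title: Bridging-Induced Attraction Simulations of Chromatin Organization
    and Transcription
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Brownian-dynamics simulations of multivalent transcription
    factors binding reversibly to a coarse-grained bead-spring chromatin
    fiber.  Bound factors cluster spontaneously (the bridging-induced
    attraction), generating loops, TAD-like and compartment-like contact
    structure, and a geometric transcription readout.  The package
    generates synthetic genome strings, runs matched wild-type/mutant
    ensembles to probe in-silico eQTL action on transcription
    probabilities genome-wide, computes contact maps and cluster
    statistics from trajectories, and provides closed-form calculators
    for dimerization equilibria, tethered local concentrations, and
    ideal-chain ("polymer melt") contact probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    igraph,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
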