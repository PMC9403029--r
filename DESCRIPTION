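Package: pocketsig
Title: Drug-Target Prediction from Positive and Negative Binding-Pocket
    Structural Signatures
Version: 0.1.0
Authors@R: person("pocketsig", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds consensus 3D structural signatures of small-molecule
    binding pockets from sets of protein structures and uses them to
    predict drug targets.  A positive signature summarises the binding
    pockets of known targets; a negative signature summarises the most
    binding-pocket-like pockets of known non-targets.  Query proteins are
    scored against both signatures with a combined structural and
    atom/residue-frequency score, and classified as targets when the
    positive score beats the negative one.  Includes a grid-based pocket
    finder, sequence-order-independent pocket alignment, a global
    sequence-similarity nearest-neighbour baseline, empirical significance
    for externally computed docking scores, and a synthetic-structure
    benchmark generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
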