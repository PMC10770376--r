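Package: erpgraph
Title: Graph Signal Processing and Spectral Graph Convolution for Event-Related EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying subject groups from multi-trial event-related
    EEG (ERP) recordings via functional connectivity graphs. Implements the full
    chain: ERP preprocessing (zero-phase band filtering, epoching, artifact
    rejection, mastoid re-referencing, baseline correction), Pearson- and
    phase-locking-value connectivity with k-nearest-neighbour graph
    sparsification, a graph-signal-processing reorganization stage (Kronecker
    random-walk network alignment and an l2,1-regularized sparse self-expressive
    graph), a Chebyshev spectral graph-convolutional classifier trained with
    subject-level cross-validation, guided-backpropagation saliency maps, ERP
    microstate analysis (global field power, k-means topography clustering with
    Krzanowski-Lai model selection), and trial-level majority voting with a
    consecutive-pair tie-break. A seeded synthetic two-group voice-ERP cohort
    generator provides ground-truth data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    signal,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
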