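Package: ristack
Title: Stacked Machine-Learning Prediction of Gas-Chromatographic Retention Indices Across Stationary Phases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts Kovats retention indices (RI) for non-polar, polar and
    mid-polar gas-chromatography stationary phases from molecular structure.
    Provides stationary-phase-aware neural base regressors (a residual
    multilayer perceptron over molecular descriptors and a character-level
    convolutional network over SMILES), transfer learning from non-polar to
    polar phases, a second-level support-vector stacking model for mid-polar
    phases and second-dimension (GCxGC) retention times, few-parameter linear
    phase-combination models, a linear functional-group-contribution baseline,
    compound-based data hygiene (stereoisomer-collapsed splits, n-alkane and
    element filters) with a full accuracy-metric suite, and an Abraham
    solvation-equation GC simulator that generates a realistic multi-phase
    retention corpus with known ground truth so every stage is trainable and
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    kernlab,
    ChemmineR,
    ChemmineOB,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    MASS
Config/testthat/edition: 3
LinkingTo:
    Rcpp
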