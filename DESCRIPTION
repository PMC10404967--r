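Package: respsound
Title: Decomposition and Classification Strategies for Respiratory Sounds
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for cycle-level classification of lung sounds
    (normal, crackle, wheeze). Implements paired-noise ensemble empirical
    mode decomposition, variational mode decomposition with
    distance-metric driven mode-number selection, multivariate
    autoregressive (Granger) features, SVM-based recursive feature
    elimination, a family of population metaheuristics (Harris hawks,
    self-adaptive differential evolution and their nested hybrid, grey
    wolf, grasshopper), extreme learning machines, K-SVD sparse
    representation classification with domain-adapting subspace
    projections, a sparse autoencoder, and stratified cross-validated
    pipelines wiring these stages together. Includes a synthetic
    lung-sound generator and readers for cycle-annotated WAV recordings
    so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    FNN,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
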