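Package: wmpriority
Title: Priority-Based Transformations of Stimulus Representations in Working Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how working-memory prioritization transforms
    stimulus representations in recurrent neural networks and EEG-like
    population data. Generates 2-back task sequences, trains small LSTM
    networks from scratch, identifies stimulus (UMI/PMI) and decision
    subspaces of population activity with a reduced-rank-regression form of
    demixed principal component analysis, and quantifies representational
    dynamics with scalar-transform traces, subspace alignment angles, and a
    bootstrap dispersion test for the disappearance of memory information.
    Includes a synthetic EEG-like data generator with planted subspaces for
    validating the analysis pipeline against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
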