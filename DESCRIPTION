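Package: miprest
Title: Mixed ICA/PCA via Reproducibility Stability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Separates a multichannel signal mixture into a nongaussian (sparse)
    subspace, a Gaussian subspace, and spurious components. Repeated FastICA
    realizations are aligned and ranked by reproducibility (RAICAR); running the
    same decomposition on many random column-decimated copies of the data
    measures how stable each component's reproducibility is as the sample size
    changes. Sparse sources are reproducible and stable, Gaussian-subspace
    components are unstable, and overextracted components are unreproducible.
    After projecting the sparse subspace out, six PCA stopping rules
    (Kaiser-Guttman, Jolliffe's modification, broken stick, information
    dimension, Horn's parallel analysis, and a permutation test) estimate the
    dimension of the residual Gaussian subspace and an orthonormal basis for it.
    Includes generators for benchmark source distributions and assignment-based
    scoring of recovered sources against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
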