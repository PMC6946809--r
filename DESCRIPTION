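Package: neurocompress
Title: Goal-Directed Neural Compression Analysis for Concept Learning fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying goal-directed dimensionality reduction in
    multivoxel fMRI activation patterns during concept learning. Implements
    PCA-based neural compression (1 - k/n with a 90% explained-variance
    criterion) mapped over the brain with a voxel-radius searchlight,
    least-squares-separate single-trial beta estimation, the SUSTAIN
    category-learning model with trial-by-trial maximum-likelihood fitting via
    differential evolution, entropy-based attention-compression indices, a
    PC-loading category-discrimination statistic, and linear mixed-effects
    group analyses of compression maps. Includes a synthetic-data generator
    that emulates the three-problem (unidimensional, XOR, parity) concept
    learning design so the full pipeline can be exercised end-to-end without
    scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
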