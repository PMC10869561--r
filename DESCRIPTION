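Package: latentMDA
Title: Multi-View Latent Feature Learning for Microbe-Disease Association Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts candidate microbe-disease associations from a sparse
    curated bipartite association matrix. Implements Gaussian interaction
    profile (GIP) kernel similarity, weighted K nearest known neighbor
    (WKNKN) matrix completion preprocessing, PCA latent features selected by
    a dominant-energy criterion, and a graph-regularized multi-view matrix
    factorization with a squared L1,2 sparsity penalty on nonnegative
    projection matrices, solved by alternating closed-form and sign-split
    multiplicative updates. Includes a leakage-safe cross-validation harness
    (global leave-one-out and repeated k-fold) with rank-based ROC/AUC, and
    a synthetic low-rank bipartite data generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), pROC, optparse, yaml, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Microbiome, Network, DimensionReduction, Software
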