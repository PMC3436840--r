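Package: pharmpkr
Title: Drug-Target Interaction Prediction from Adverse-Event Side-Effect Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds drug side-effect profiles from quarterly adverse-event
    report files (FDA AERS dialect), computes weighted-cosine pharmacological
    similarity between drugs, and predicts drug-target interactions with a
    pairwise kernel regression model whose tensor-product factorization gives
    a closed-form solution in the two marginal kernels. Includes surrogate
    chemical (Tanimoto fingerprint) and genomic (normalized Smith-Waterman)
    kernels, kernel integration, pair-wise and block-wise cross-validation
    with AUC/AUPR, single-linkage representative-drug selection, and a
    seeded synthetic-data generator emulating every input format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
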