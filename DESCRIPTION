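Package: fegsForest
Title: Graphical Protein Sequence Features and Cascade Forest Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Binary protein sequence classification from graphical and
    statistical descriptors. Implements the FEGS featurizer (per-property 3D
    cone curves, distance-quotient matrices and their leading eigenvalues,
    concatenated with amino-acid and dipeptide composition; 578 dimensions at
    the default 158 physicochemical properties), the amphiphilic pseudo
    amino-acid composition (APAAC) and dipeptide composition baselines, and a
    cascade deep-forest classifier (layers of boosted trees, random forests
    and extremely randomized trees with out-of-fold class-probability
    augmentation and stop-on-no-improvement). Includes stratified k-fold
    cross-validation with confusion-matrix metrics and ROC AUC, a seeded
    first-order Markov generator of two-class synthetic protein datasets, and
    a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    seqinr,
    xgboost,
    ranger,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
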