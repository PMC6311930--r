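Package: hcnsadr
Title: Adverse Drug Reaction Prediction for Combined Medication with
    Highly-Credible Negative Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts adverse drug reactions (ADRs) of pair-wise combined
    medication. Drugs are encoded as concatenated binary feature vectors
    over chemical substructures, target proteins, substituents and
    pathways; candidate drug pairs are scored on a drug-disease-gene
    tripartite network and the lowest-scoring pairs are selected as
    highly-credible negative training samples; one binary classifier per
    ADR is trained on PCA-reduced pair vectors and evaluated with
    stratified cross-validation and macro-averaged metrics. Includes
    random-negative, random-assignment and one-class SVM baselines, a
    synthetic fixture generator with planted interaction structure, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    class,
    e1071,
    jsonlite,
    pROC,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
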