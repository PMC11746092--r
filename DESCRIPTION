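Package: epibench
Title: Simulation and Benchmarking of Linear and Non-Linear Genotype
    Risk Models Under Epistasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates case-control genotype cohorts whose disease
    probability mixes a logistic polygenic-score component with a pure
    epistatic component defined by a penetrance table, constructs two- and
    three-locus penetrance tables (additive, multiplicative and threshold
    interaction forms) that attain a requested broad-sense heritability on
    the observed binary scale, computes the theoretical AUC-ROC of the
    generative model, and benchmarks linear against non-linear classifiers
    (L1-penalised logistic regression, random forests, gradient-boosted
    trees, and small feed-forward, convolutional and recurrent neural
    networks) under a repeated stratified holdout protocol.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    glmnet,
    ranger,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
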