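Package: grsforge
Title: Tree-Based Construction and Evaluation of Genetic Risk Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction of genetic risk scores (GRS) for binary traits from
    SNP genotype data using tree-based statistical learning: logic regression
    over Boolean trees (greedy and simulated-annealing search), bagged logic
    regression ensembles, probability-estimation random forests with and
    without shadow-variable (Boruta-style) importance selection, and
    elastic-net penalized logistic regression as a linear reference. Includes
    a three-scenario case-control SNP simulator (marginal effects, gene-gene
    interactions, gene-environment interactions with interquartile-range
    scaled odds ratios), association testing of logit-transformed risk
    scores via Wald tests, AUC and classification metrics, and an experiment
    harness implementing a cyclic train/validation/test scheme with joint
    hyperparameter tuning, power and type-I-error estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ranger
Config/testthat/edition: 3
RoxygenNote: 7.3.3
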