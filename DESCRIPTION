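Package: epigain
Title: Epistasis Detection in Case-Control GWAS via Ensemble Ranking and
    Information Gain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for detecting gene-gene interactions in
    case-control genotype data: per-sample and per-marker quality control
    (missingness, minor allele frequency, Hardy-Weinberg equilibrium,
    greedy linkage-disequilibrium pruning, mode imputation); TuRF
    (Tuned ReliefF) interaction-sensitive feature filtering with a
    mean + k*SD selection threshold; a dual tree-ensemble ranking harness
    (repeated stratified cross-validation over a parameter grid for a
    random forest and a gradient-boosted machine behind a learner-adapter
    contract, with per-sample accuracy, rank-based AUC, importance
    averaging and two-method consensus selection); and plug-in
    information-theoretic two-way and three-way interaction analysis
    (mutual information, information gain in bits and as percent of
    phenotype entropy) with permutation significance testing. A
    penetrance-model simulator generates case-control genotype data with
    planted main-effect or pure-epistasis architecture so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ranger,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
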