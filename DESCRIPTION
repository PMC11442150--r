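Package: DrugReSC
Title: Drug Repurposing by Signature Reversal in Single Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ranks candidate drugs for a disease phenotype from single-cell
    RNA-seq data. A gene-by-cell log-expression matrix is transformed into a
    drug-by-cell matrix of reversal (D2C) scores via a rank-weighted
    single-sample enrichment walk over each drug instance's up- and
    down-regulated gene signatures. Drug instances are then ranked by their
    contribution to classifying disease-associated versus other cells, by
    default via out-of-bag permutation importance in a random forest, with
    Wilcoxon rank-sum, ANOVA/Welch, L1-penalised logistic regression, SVM
    sensitivity and gradient-boosting backends and a cross-method vote.
    Includes balanced negative-sampling evaluation (AUROC, AUPR, F1,
    accuracy) and a synthetic-data generator with planted reversal drugs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    randomForest,
    glmnet,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    e1071,
    xgboost,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
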