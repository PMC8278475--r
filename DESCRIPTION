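Package: stackomics
Title: Multi-Omics Integration, Hierarchical Feature Selection and a
    Stacked Probability Ensemble for Tumor Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates protein-coding expression, non-coding RNA expression
    and CpG methylation beta values into one sample-aligned triple dataset,
    reduces it by a three-stage hierarchical feature selection (CpG-to-gene
    beta aggregation, fold-change with Benjamini-Hochberg FDR filtering, and
    greedy minimum-redundancy maximum-relevance selection on three-state
    discretized data), and classifies tumor versus normal samples with a
    second-learning stacked ensemble: four heterogeneous base classifiers
    (RBF-kernel SVM, decision tree, random forest, AdaBoost) whose
    out-of-fold class probabilities are re-learned by a gradient-boosted
    tree meta-learner. Includes a synthetic triple-omics data generator with
    planted effects, nested cross-validation, a feature-count sweep, and
    confusion-matrix metrics reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    e1071,
    rpart,
    randomForest,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
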