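---
title: "Hierarchical feature selection and probability stacking for multi-omics tumor classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical feature selection and probability stacking for multi-omics tumor classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Tumor/normal classification from a single omics layer discards
information: protein-coding expression, ncRNA expression and DNA
methylation capture partly disjoint aspects of carcinogenesis, and
methylation in particular is tied to genes through a many-to-many
probe–gene relation that plain feature selectors treat as redundancy.
`stackomics` implements a pipeline that (i) integrates the three layers
into one sample-aligned *triple dataset*, (ii) reduces it hierarchically —
unsupervised CpG-to-gene aggregation, then univariate fold-change/FDR
screening, then multivariate mRMR — and (iii) classifies with a stacked
ensemble whose meta-learner is trained on the out-of-fold class
probabilities of four heterogeneous base classifiers, i.e. on data that
embeds each classifier's probability errors.

The pipeline assumes: nonnegative count-scale expression (tested on
log2(x+1)); methylation given as beta values in [0,1], already a bounded
ratio and therefore neither normalized nor log-transformed; binary labels
derivable from TCGA barcodes (type `01` positive, `11` negative) or an
explicit label table; and two classes present in every learning set.

```{r, eval = FALSE}
library(stackomics)
sim <- simulate_triple(synth_spec(seed = 14))
res <- run_nested_cv(sim$dataset, pipeline_config(n = 10, seed = 14),
                     map = sim$map)
res$pooled
```

## Parameters that matter

* **Stage-2 thresholds** (`log2fc_meth = 0.5`, `log2fc_expr = 3`,
  `fdr = 0.05`): the standard screening levels for this design;
  methylated-gene means move on the compressed [0,1] beta scale, hence the
  much lower fold-change bar. Inequalities are strict (`>`/`<`).
* **Discretization `k = 0.5`** (dimensionless): a value is ±2 when at
  least half a standard deviation from the feature mean, else 0. The
  standard deviation is the population (÷N) form; a sample-sd variant is
  available (`sd_type`). Boundaries are inclusive toward ±2.
* **mRMR feature count `n`**: swept over 5..30 by
  `sweep_feature_count()`, which refits the whole nested CV per `n` and
  takes the *first* accuracy peak — beyond it, added features carry more
  noise than signal.
* **Folds** `F_outer = 10`, `K_inner = 5`: 10-fold outer CV is the
  evaluation protocol; the inner subset count is a free choice (5 keeps
  every inner training set usable at small n). Outer folds are plain
  random by default; `stratify = TRUE` preserves class ratios, useful when
  normals are scarce.
* **Base-learner grids**: SVM (RBF) C ∈ {0.001, 0.01, 0.1},
  gamma ∈ {1, 10, 100}; random forest n_estimators ∈ {50, 100}; AdaBoost
  n_estimators = 50; decision tree at its defaults. Grid points are scored
  by mean inner-CV accuracy, ties going to the first declared point.
* **Meta-learner**: gradient-boosted trees, rounds chosen from
  {100, 200, 300} by CV on the meta-dataset; decision threshold 0.5.

## The synthetic generator

`synth_spec()` emulates the data regime the pipeline targets at desk
scale: an imbalanced two-class cohort (60 tumor / 20 normal), 2,000
protein-coding + 1,000 ncRNA features as negative-binomial counts
(gamma–Poisson, dispersion 0.3, baseline means spread two log2 units
around 100), and 500 methylated genes measured through ~3 Beta-distributed
probes each (precision φ = 30), with 20% of probes shared by a second gene
so the many-to-many relation is exercised. Planted effects are 50/25/25
differential features per block with |log2FC| = 4 (sign alternating) and a
+0.3 beta shift in tumors; probe values are generated around the
gene-level mean, so mean aggregation is the correct recovery operator by
construction. Real 450K/HTSeq data differ in ways the generator does not
model — batch effects, correlated co-expression modules, probe-specific
offsets, label noise, and two orders of magnitude more features — so
passing tests demonstrate algorithmic correctness and sane statistical
behavior, not clinical performance.

## Numerical and procedural choices

* **Aliquot tie-break**: when a patient contributes several samples of the
  same type code, the lexicographically smallest barcode is kept —
  deterministic and assay-independent.
* **Cross-block join key**: patient ID + type code, because aliquot fields
  differ between assays of the same sample.
* **Normalization**: expression blocks are quantile-normalized across
  samples (`limma::normalizeQuantiles`); beta matrices are left as-is.
  `normalization = "none"` switches it off.
* **Missingness**: only features missing in 100% of samples are dropped;
  partial missingness is mean-imputed (no imputation method is prescribed
  by the design, and the mean is scale-free).
* **Per-feature test**: the test behind the FDR step is a two-sided Welch
  t-test (constant features get p = 1); a Wilcoxon option exists. BH
  adjustment (`stats::p.adjust`) runs within the pooled expression table
  and the methylated-gene table separately, since their thresholds differ;
  step-up q-values are checked in the test suite against the definitional
  min-over-tails oracle.
* **mRMR search**: the max-relevance/min-redundancy objective is a set
  objective with no prescribed search; exhaustive search is intractable,
  so the canonical greedy incremental form is used (relevance minus mean
  redundancy against the current set). Mutual information is the plug-in
  estimate in bits with 0·log 0 = 0, clamped at 0 against rounding. Ties
  in the greedy score break by input feature order, with scores within
  1e-9 bits treated as tied so floating-point summation order cannot
  override the rule. Zero-variance features discretize to all-zeros (both
  boundary inequalities hold; the uninformative state is the only
  consistent resolution).
* **Leakage control**: CpG aggregation is unsupervised and computed once;
  stage-2 statistics, discretization statistics, mRMR, grid tuning and the
  meta-dataset are all computed inside each outer fold's learning set
  only. The out-of-fold contract — no meta row predicted by a model
  trained on it — is asserted in tests with instrumented stub learners.
* **Stacking for new samples**: test-fold meta-features come from base
  learners retrained on the entire learning set with their tuned
  parameters, the standard stacked-generalization completion of the
  condensed procedure.
* **Meta-learner regularization**: with only one probability column per
  base learner, a deep boosted model can lock onto a single column that
  happens to separate the out-of-fold data perfectly, making the ensemble
  hostage to that one classifier on new samples. The meta fit therefore
  uses shallow trees (`max_depth = 2`) and samples one column per boosting
  round (`colsample_bytree = 1/4` with the default learners), spreading
  weight across all base classifiers; rounds are still selected from
  {100, 200, 300}.
* **SVM probabilities** come from the Platt-style calibration built into
  probability-mode training — an approximation; its internal CV consumes
  RNG, so fits are seeded explicitly everywhere for bit-reproducibility.
* **Repetition rate** (feature stability) is defined here as the mean over
  folds of the fraction of a fold's features that appear in at least two
  folds overall; a mean pairwise Jaccard variant is available
  (`rate = "jaccard"`).

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the generator at its default
desk scale (80 samples, 3,000 expression features, ~1,500 probes over 500
genes) for the end-to-end benchmark, with 10 outer folds and n = 10 mRMR
features; unit tests use smaller matrices chosen so that every oracle can
be recomputed by brute force. The n = 5..30 sweep is exercised on a
reduced range in tests, since each sweep point refits the entire nested
CV.

## Known limitations

* Feature IDs are assumed unique across blocks; a gene symbol appearing
  both as an expression feature and as a methylated gene would collide in
  the combined design matrix (prefix one block's IDs if this arises).
* AdaBoost is implemented in-package (SAMME with depth-1 stumps, weighted
  vote probabilities); its probability estimates are coarser than those of
  the other learners.
* The stage-2 t-test is unmoderated; with very few samples per class an
  empirical-Bayes test would be more powerful.
* Beta values are analyzed on the beta scale throughout; M-value
  transformation and DMR calling are out of scope, as are IDAT inputs,
  batch correction and multi-class diagnosis.
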