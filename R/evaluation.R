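#' Confusion-matrix counts for binary tumor/normal predictions
#'
#' Primary tumor (`+1`) is the positive class, solid tissue normal (`-1`)
#' the negative class.
#'
#' @param y_true,y_pred Equal-length label vectors in `{-1, +1}`.
#' @return List of class `confusion_matrix` with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred),
            all(y_true %in% c(-1, 1)), all(y_pred %in% c(-1, 1)))
  structure(list(tp = sum(y_true == 1 & y_pred == 1),
                 tn = sum(y_true == -1 & y_pred == -1),
                 fp = sum(y_true == -1 & y_pred == 1),
                 fn = sum(y_true == 1 & y_pred == -1)),
            class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy `(TP + TN) / total`, sensitivity (recall) `TP / (TP + FN)`,
#' specificity `TN / (TN + FP)` and F1 `2 TP / (2 TP + FP + FN)`, reported
#' as percentages at full precision (display rounds to two decimals).
#' Undefined ratios (empty denominators; F1 with `TP = FP = FN = 0`) are
#' reported as `NA`.
#'
#' @param cm A `confusion_matrix` or list with `tp`, `tn`, `fp`, `fn`.
#' @return List of class `metrics_report`: `accuracy`, `sensitivity`,
#'   `specificity`, `f1` (percent), and `confusion`.
#' @export
metrics <- function(cm) {
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  if (total == 0) stop("empty confusion matrix")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    accuracy = 100 * (cm$tp + cm$tn) / total,
    sensitivity = 100 * ratio(cm$tp, cm$tp + cm$fn),
    specificity = 100 * ratio(cm$tn, cm$tn + cm$fp),
    f1 = 100 * ratio(2 * cm$tp, 2 * cm$tp + cm$fp + cm$fn),
    confusion = cm), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.2f%%", v)
  cat(sprintf("accuracy %s  sensitivity %s  specificity %s  F1 %s\n",
              fmt(x$accuracy), fmt(x$sensitivity), fmt(x$specificity),
              fmt(x$f1)))
  cat(sprintf("  [tn=%d fp=%d | fn=%d tp=%d]\n", x$confusion$tn,
              x$confusion$fp, x$confusion$fn, x$confusion$tp))
  invisible(x)
}

#' Pipeline configuration with the study defaults
#'
#' Collects every tunable of the end-to-end pipeline. Defaults follow the
#' study settings: 10 outer folds, discretization `k = 0.5`, feature-count
#' sweep 5..30, screening thresholds `|log2FC| > 0.5` (methylated genes) /
#' `> 3` (expression) with `FDR < 0.05`, and the base-learner grids of
#' [base_learner_spec()].
#'
#' @param F_outer,K_inner Outer fold and inner subset counts.
#' @param n Fixed mRMR feature count; `NULL` means sweep `n_range`.
#' @param n_range Candidate feature counts for [sweep_feature_count()].
#' @param k Discretization threshold parameter.
#' @param log2fc_meth,log2fc_expr,fdr Stage-2 screening thresholds.
#' @param test Per-feature test, `"welch_t"` or `"wilcoxon"`.
#' @param normalization Expression normalization, `"quantile"` or `"none"`.
#' @param use_pc,use_nc,use_meth Block toggles (ablation).
#' @param use_cpg_agg Aggregate CpG probes to genes before stage 2 (stage-1 reduction).
#' @param stratify Stratified outer folds.
#' @param threshold Decision threshold on the ensemble probability.
#' @param meta_grid Boosting-round grid for the meta-learner.
#' @param learners Base learner specs, default [default_base_learners()].
#' @param seed Pipeline seed; all randomness flows from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(F_outer = 10, K_inner = 5, n = NULL,
                            n_range = 5:30, k = 0.5,
                            log2fc_meth = 0.5, log2fc_expr = 3, fdr = 0.05,
                            test = "welch_t",
                            normalization = "quantile",
                            use_pc = TRUE, use_nc = TRUE, use_meth = TRUE,
                            use_cpg_agg = TRUE, stratify = FALSE,
                            threshold = 0.5, meta_grid = c(100, 200, 300),
                            learners = default_base_learners(),
                            seed = 14L) {
  if (!any(use_pc, use_nc, use_meth)) stop("at least one block must be enabled")
  structure(list(F_outer = F_outer, K_inner = K_inner, n = n,
                 n_range = n_range, k = k, log2fc_meth = log2fc_meth,
                 log2fc_expr = log2fc_expr, fdr = fdr, test = test,
                 normalization = normalization, use_pc = use_pc,
                 use_nc = use_nc, use_meth = use_meth,
                 use_cpg_agg = use_cpg_agg, stratify = stratify,
                 threshold = threshold, meta_grid = meta_grid,
                 learners = learners, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Assemble the analysis view of a triple dataset: CpG aggregation on the probe block
# (when enabled), block toggles applied. Returns raw blocks (for stage-2
# statistics on the original scale) and a combined classifier matrix on the
# log2(count + 1) / beta scale, samples in rows.
prepare_blocks <- function(dataset, map = NULL, config) {
  blocks <- dataset$blocks
  if (config$use_meth && config$use_cpg_agg &&
      all(blocks$meth$feature_type == "cpg_probe")) {
    if (is.null(map)) stop("CpG aggregation requires a probe_gene_map")
    blocks$meth <- aggregate_cpg_to_genes(blocks$meth, map)
  }
  keep <- c(pc = config$use_pc, nc = config$use_nc, meth = config$use_meth)
  blocks <- blocks[names(keep)[keep]]
  expr_scaled <- lapply(blocks, function(b) {
    if (b$data_scale == "counts") log2(b$values + 1) else b$values
  })
  X <- t(do.call(rbind, expr_scaled))
  types <- unlist(lapply(blocks, `[[`, "feature_type"), use.names = FALSE)
  names(types) <- unlist(lapply(blocks, function(b) rownames(b$values)))
  list(blocks = blocks, X = X, feature_types = types)
}

# Stage 2 on the learning partition only: expression blocks pooled for one
# BH adjustment, methylated genes adjusted separately (their threshold and
# scale differ). Returns the combined record table with `selected`.
stage2_select <- function(blocks, y, idx, config) {
  tabs <- list()
  expr <- blocks[names(blocks) %in% c("pc", "nc")]
  if (length(expr)) {
    vals <- do.call(rbind, lapply(expr, function(b)
      b$values[, idx, drop = FALSE]))
    types <- unlist(lapply(expr, `[[`, "feature_type"), use.names = FALSE)
    em <- omics_matrix(vals, feature_type = types, data_scale = "counts",
                       samples = expr[[1]]$samples[idx, , drop = FALSE])
    tabs$expr <- differential_table(em, y[idx], test = config$test)
  }
  if ("meth" %in% names(blocks)) {
    b <- blocks$meth
    mm <- omics_matrix(b$values[, idx, drop = FALSE],
                       feature_type = b$feature_type, data_scale = "beta",
                       samples = b$samples[idx, , drop = FALSE])
    tabs$meth <- differential_table(mm, y[idx], test = config$test)
  }
  records <- do.call(rbind, tabs)
  rownames(records) <- NULL
  select_differential(records, log2fc_meth = config$log2fc_meth,
                      log2fc_expr = config$log2fc_expr, fdr = config$fdr)
}

#' Run the full pipeline under nested cross-validation
#'
#' Splits the samples into `F` outer folds; within each fold, stage-2
#' screening (fold change + FDR) and stage-3 mRMR run on the learning
#' partition only, the four base learners are grid-tuned on inner subsets,
#' the stacked ensemble is trained on the learning set, and the held-out
#' test fold is predicted once. CpG-to-gene aggregation, being
#' unsupervised, is computed once up front. Discretization statistics are
#' fitted on learning samples only.
#'
#' When stage 2 yields fewer than `n` survivors, the shortfall is filled
#' with the smallest-q non-selected features so mRMR always sees `n`
#' candidates or everything available.
#'
#' @param dataset A `triple_dataset` (the `meth` block may be probe-level,
#'   in which case `map` is required for aggregation).
#' @param config A [pipeline_config()]; `config$n` must be set (use
#'   [sweep_feature_count()] to choose it).
#' @param map Optional `probe_gene_map` for the CpG aggregation.
#' @return List of class `nested_cv_result`: `pooled` (pooled
#'   `metrics_report`), `per_fold` (fold metrics), `fold_features`
#'   (selected IDs per fold), `feature_types`, `predictions` (data frame:
#'   sample, fold, truth, probability, prediction), `config`.
#' @export
run_nested_cv <- function(dataset, config, map = NULL) {
  if (is.null(config$n)) stop("config$n is not set; run sweep_feature_count() or fix n")
  prep <- prepare_blocks(dataset, map, config)
  y <- unname(dataset$y)
  n_samples <- length(y)
  plan <- make_fold_plan(n_samples, config$F_outer, config$K_inner,
                         seed = config$seed, stratify = config$stratify,
                         y = y)
  fold_features <- vector("list", config$F_outer)
  per_fold <- vector("list", config$F_outer)
  pred_all <- data.frame()
  for (f in seq_len(config$F_outer)) {
    learn <- which(plan$outer != f)
    test <- which(plan$outer == f)
    if (length(unique(y[learn])) < 2L)
      stop("outer fold ", f, " has a single-class learning set")
    records <- stage2_select(prep$blocks, y, learn, config)
    sel <- records$feature_id[records$selected]
    n_f <- min(config$n, nrow(records))
    if (length(sel) < n_f) {
      rest <- records[!records$selected, ]
      sel <- c(sel, rest$feature_id[order(rest$q_value)][seq_len(n_f - length(sel))])
    }
    Xl <- prep$X[learn, sel, drop = FALSE]
    disc <- discretize(t(Xl), k = config$k)
    mr <- mrmr_select(disc, y[learn], n = min(n_f, length(sel)))
    feats <- mr$selected
    fold_features[[f]] <- feats
    inner <- plan$inner[[f]]
    ens <- train_ensemble(prep$X[learn, feats, drop = FALSE], y[learn],
                          specs = config$learners,
                          inner = unname(inner),
                          meta_grid = config$meta_grid,
                          threshold = config$threshold,
                          seed = config$seed + 1000L + f)
    pr <- predict(ens, prep$X[test, feats, drop = FALSE])
    cm <- confusion(y[test], pr$label)
    per_fold[[f]] <- metrics(cm)
    pred_all <- rbind(pred_all, data.frame(
      sample = rownames(prep$X)[test], fold = f, truth = y[test],
      probability = pr$probability, prediction = pr$label))
  }
  pooled_cm <- confusion(pred_all$truth, pred_all$prediction)
  structure(list(pooled = metrics(pooled_cm), per_fold = per_fold,
                 fold_features = fold_features,
                 feature_types = prep$feature_types,
                 predictions = pred_all, config = config),
            class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat(sprintf("<nested_cv_result> %d outer folds, n = %d features/fold\n",
              length(x$per_fold), x$config$n))
  cat("pooled: "); print(x$pooled)
  invisible(x)
}

#' Sweep the mRMR feature count and pick the first accuracy peak
#'
#' Runs the full nested CV once per candidate `n` and returns the mean
#' cross-validated accuracy curve. The optimal `n` is the smallest value
#' attaining the maximum accuracy (the first peak), on the grounds that
#' features added beyond it contribute more noise than signal.
#'
#' @param dataset,config,map As in [run_nested_cv()].
#' @param n_range Candidate feature counts (default `config$n_range`).
#' @return List of class `sweep_result`: `curve` (data frame `n`,
#'   `mean_accuracy`), `optimal_n`, `runs` (per-`n` results).
#' @export
sweep_feature_count <- function(dataset, config, map = NULL,
                                n_range = NULL) {
  n_range <- n_range %||% config$n_range
  runs <- lapply(n_range, function(n) {
    cfg <- config
    cfg$n <- n
    run_nested_cv(dataset, cfg, map = map)
  })
  acc <- vapply(runs, function(r)
    mean(vapply(r$per_fold, `[[`, numeric(1), "accuracy")), numeric(1))
  curve <- data.frame(n = n_range, mean_accuracy = acc)
  optimal_n <- n_range[which.max(acc)]  # first max = smallest such n
  structure(list(curve = curve, optimal_n = optimal_n, runs = runs),
            class = "sweep_result")
}

#' Per-fold feature stability report
#'
#' Summarizes the feature lists selected in each outer fold: the union
#' after removing overlaps, per-category counts, the epigenetic fraction
#' (ncRNA plus methylated genes over the union), and the repetition rate —
#' by default the mean over folds of the fraction of that fold's features
#' that appear in at least two folds overall. A mean pairwise Jaccard
#' alternative is available.
#'
#' @param fold_lists List of per-fold feature ID vectors.
#' @param feature_types Named vector mapping feature IDs to their category
#'   (`protein_coding`, `ncRNA`, `methylated_gene`).
#' @param rate One of `"recurrence"` (default) or `"jaccard"`.
#' @return List of class `feature_report`: `union`, `counts_by_type`,
#'   `epigenetic_fraction`, `repetition_rate`, `occurrences`.
#' @export
feature_stability <- function(fold_lists, feature_types = NULL,
                              rate = c("recurrence", "jaccard")) {
  rate <- match.arg(rate)
  stopifnot(length(fold_lists) > 0)
  occ <- table(unlist(lapply(fold_lists, unique)))
  union_ids <- names(occ)
  rep_rate <- if (rate == "recurrence") {
    100 * mean(vapply(fold_lists, function(fl)
      mean(occ[fl] >= 2), numeric(1)))
  } else {
    pairs <- utils::combn(length(fold_lists), 2)
    100 * mean(apply(pairs, 2, function(ij) {
      a <- fold_lists[[ij[1]]]; b <- fold_lists[[ij[2]]]
      length(intersect(a, b)) / length(union(a, b))
    }))
  }
  counts <- NULL
  epi <- NA_real_
  if (!is.null(feature_types)) {
    cats <- feature_types[union_ids]
    counts <- table(factor(cats, levels = c("protein_coding", "ncRNA",
                                            "methylated_gene")))
    epi <- 100 * sum(counts[c("ncRNA", "methylated_gene")]) / length(union_ids)
  }
  structure(list(union = union_ids, counts_by_type = counts,
                 epigenetic_fraction = epi, repetition_rate = rep_rate,
                 occurrences = occ),
            class = "feature_report")
}

#' Ablation comparison over block combinations
#'
#' Re-runs the nested CV for each requested combination of the three
#' blocks (singles, pairs, and the full triple) and tabulates the pooled
#' metrics, quantifying what each data type contributes.
#'
#' @param dataset,config,map As in [run_nested_cv()].
#' @param combos List of character vectors over `c("pc", "nc", "meth")`;
#'   default: the 7 non-empty combinations.
#' @return Data frame: `combo`, `accuracy`, `sensitivity`, `specificity`,
#'   `f1`.
#' @export
run_ablation <- function(dataset, config, map = NULL, combos = NULL) {
  if (is.null(combos)) {
    all_blocks <- c("pc", "nc", "meth")
    combos <- unlist(lapply(1:3, function(k)
      utils::combn(all_blocks, k, simplify = FALSE)), recursive = FALSE)
  }
  rows <- lapply(combos, function(cb) {
    cfg <- config
    cfg$use_pc <- "pc" %in% cb
    cfg$use_nc <- "nc" %in% cb
    cfg$use_meth <- "meth" %in% cb
    res <- run_nested_cv(dataset, cfg, map = map)
    data.frame(combo = paste(cb, collapse = "+"),
               accuracy = res$pooled$accuracy,
               sensitivity = res$pooled$sensitivity,
               specificity = res$pooled$specificity,
               f1 = res$pooled$f1)
  })
  do.call(rbind, rows)
}
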