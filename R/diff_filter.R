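#' Per-feature fold change between tumor and normal groups
#'
#' The fold change of a feature is the ratio of its tumor-group mean to
#' its normal-group mean, with a pseudocount added to both means to keep
#' the ratio finite on sparse counts. For count-scale data the default
#' pseudocount is 1; beta values are bounded away from zero in practice,
#' so their default is 0.
#'
#' @param block An `omics_matrix` (nonnegative values) or a plain numeric
#'   matrix, features in rows.
#' @param y Label vector in `{-1, +1}`, one per sample column.
#' @param pseudocount Nonnegative value added to both group means.
#' @return Data frame with `feature_id`, `mean_tumor`, `mean_normal`,
#'   `fc`, `log2fc`.
#' @export
fold_change <- function(block, y, pseudocount = NULL) {
  v <- if (inherits(block, "omics_matrix")) block$values else block
  if (is.null(pseudocount))
    pseudocount <- if (inherits(block, "omics_matrix") &&
                       block$data_scale == "beta") 0 else 1
  stopifnot(ncol(v) == length(y), all(y %in% c(-1, 1)))
  if (min(v, na.rm = TRUE) < 0) stop("fold change requires nonnegative values")
  mt <- rowMeans(v[, y == 1, drop = FALSE], na.rm = TRUE)
  mn <- rowMeans(v[, y == -1, drop = FALSE], na.rm = TRUE)
  fc <- (mt + pseudocount) / (mn + pseudocount)
  data.frame(feature_id = rownames(v), mean_tumor = mt, mean_normal = mn,
             fc = fc, log2fc = log2(fc), row.names = NULL,
             stringsAsFactors = FALSE)
}

# Vectorized two-sided Welch t-test across matrix rows. Constant rows
# (zero variance in both groups) get p = 1 by convention.
row_welch_t <- function(v, y) {
  g1 <- v[, y == 1, drop = FALSE]
  g2 <- v[, y == -1, drop = FALSE]
  n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
  if (any(n1 < 2) || any(n2 < 2)) stop("each class needs >= 2 samples per feature")
  m1 <- rowMeans(g1, na.rm = TRUE); m2 <- rowMeans(g2, na.rm = TRUE)
  s1 <- apply(g1, 1, stats::var, na.rm = TRUE)
  s2 <- apply(g2, 1, stats::var, na.rm = TRUE)
  se2 <- s1 / n1 + s2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  p[se2 == 0] <- 1
  p
}

#' Per-feature two-group significance test
#'
#' Two-sided Welch two-sample t-test per feature (default), computed on
#' `log2(x + 1)` for count-scale blocks and on raw values otherwise.
#' Features with zero variance in both groups get p = 1. A Wilcoxon
#' rank-sum alternative is available.
#'
#' @inheritParams fold_change
#' @param test `"welch_t"` (default) or `"wilcoxon"`.
#' @return Numeric vector of p-values, one per feature.
#' @export
per_feature_test <- function(block, y, test = c("welch_t", "wilcoxon")) {
  test <- match.arg(test)
  v <- if (inherits(block, "omics_matrix")) block$values else block
  stopifnot(ncol(v) == length(y), all(y %in% c(-1, 1)))
  if (sum(y == 1) < 2 || sum(y == -1) < 2)
    stop("need >= 2 samples per class")
  if (inherits(block, "omics_matrix") && block$data_scale == "counts")
    v <- log2(v + 1)
  if (test == "welch_t") return(row_welch_t(v, y))
  apply(v, 1, function(x) {
    if (stats::var(x) == 0) return(1)
    stats::wilcox.test(x[y == 1], x[y == -1], exact = FALSE)$p.value
  })
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Step-up q-values: with p-values sorted ascending,
#' `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1 and mapped back to
#' the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Build the per-feature differential table for one block
#'
#' Combines [fold_change()], [per_feature_test()] and [bh_adjust()] into
#' the stage-2 record table. BH adjustment is applied within the table
#' (callers pool expression blocks before calling when pooled adjustment
#' is wanted).
#'
#' @inheritParams fold_change
#' @inheritParams per_feature_test
#' @return Data frame: `feature_id`, `feature_type`, `mean_tumor`,
#'   `mean_normal`, `fc`, `log2fc`, `p_value`, `q_value`.
#' @export
differential_table <- function(block, y, pseudocount = NULL,
                               test = "welch_t") {
  fcdf <- fold_change(block, y, pseudocount = pseudocount)
  fcdf$feature_type <- if (inherits(block, "omics_matrix"))
    block$feature_type else "unknown"
  fcdf$p_value <- per_feature_test(block, y, test = test)
  fcdf$q_value <- bh_adjust(fcdf$p_value)
  fcdf[, c("feature_id", "feature_type", "mean_tumor", "mean_normal",
           "fc", "log2fc", "p_value", "q_value")]
}

#' Select significantly differential features
#'
#' Applies the per-datatype screening thresholds: methylated genes pass
#' with `|log2FC| > 0.5` and `q < 0.05`; expression features
#' (protein-coding and ncRNA) with `|log2FC| > 3` and `q < 0.05`.
#' Inequalities are strict.
#'
#' @param records Differential table(s) as from [differential_table()]
#'   (multiple blocks may be row-bound).
#' @param log2fc_meth,log2fc_expr Absolute log2 fold-change thresholds.
#' @param fdr FDR (q-value) threshold.
#' @return `records` with a logical `selected` column added.
#' @export
select_differential <- function(records, log2fc_meth = 0.5,
                                log2fc_expr = 3, fdr = 0.05) {
  thr <- ifelse(records$feature_type == "methylated_gene",
                log2fc_meth, log2fc_expr)
  records$selected <- abs(records$log2fc) > thr & records$q_value < fdr
  records
}
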