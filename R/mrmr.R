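#' Three-state discretization for mutual-information estimation
#'
#' Maps each value of each feature to one of three states by its distance
#' from the feature mean in units of `k` standard deviations:
#' state `+2` when `x >= mean + k * sd`, state `-2` when
#' `x <= mean - k * sd`, state `0` otherwise (both boundaries inclusive
#' toward the extreme states). The standard deviation is the population
#' (divide-by-N) form by default. A zero-variance feature makes both
#' boundary conditions true at every point; the tie resolves to the
#' uninformative state 0.
#'
#' Passing `fit_stats` applies previously fitted per-feature means and
#' standard deviations, the held-out-transform contract used inside
#' cross-validation.
#'
#' @param x Numeric matrix, features in rows, or an `omics_matrix`.
#' @param k Positive threshold parameter (default 0.5).
#' @param fit_stats Optional data frame with columns `feature_id`, `mean`,
#'   `sd` from a previous fit.
#' @param sd_type `"population"` (divide by N, default) or `"sample"`.
#' @return List of class `discrete_matrix`: `states` (integer matrix over
#'   `{-2, 0, 2}`), `stats` (per-feature `feature_id`, `mean`, `sd`, `k`).
#' @export
discretize <- function(x, k = 0.5, fit_stats = NULL,
                       sd_type = c("population", "sample")) {
  if (inherits(x, "omics_matrix")) x <- x$values
  stopifnot(is.matrix(x), k > 0)
  sd_type <- match.arg(sd_type)
  if (is.null(fit_stats)) {
    mu <- rowMeans(x)
    dev <- x - mu
    n <- ncol(x)
    denom <- if (sd_type == "population") n else n - 1L
    sdv <- sqrt(rowSums(dev * dev) / denom)
    fit_stats <- data.frame(feature_id = rownames(x), mean = mu, sd = sdv,
                            row.names = NULL, stringsAsFactors = FALSE)
  } else {
    idx <- match(rownames(x), fit_stats$feature_id)
    if (anyNA(idx)) stop("fit_stats missing features: ",
                         paste(utils::head(rownames(x)[is.na(idx)]), collapse = ", "))
    mu <- fit_stats$mean[idx]
    sdv <- fit_stats$sd[idx]
  }
  hi <- x >= mu + k * sdv
  lo <- x <= mu - k * sdv
  states <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  states[hi & !lo] <- 2L
  states[lo & !hi] <- -2L  # hi & lo (sd = 0) stays 0
  if (any(sdv == 0))
    message(sum(sdv == 0), " zero-variance feature(s) discretized to all-0")
  fit_stats$k <- k
  structure(list(states = states, stats = fit_stats),
            class = "discrete_matrix")
}

#' Plug-in mutual information of two discrete vectors, in bits
#'
#' Empirical estimate `sum p(a,b) * log2(p(a,b) / (p(a) p(b)))` over the
#' joint contingency table, with the `0 * log 0 = 0` convention. Tiny
#' negative rounding is clamped to zero.
#'
#' @param a,b Equal-length vectors over finite alphabets.
#' @return Mutual information in bits (nonnegative).
#' @export
mutual_information <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) == 0L) stop("vectors must be non-empty")
  tab <- table(a, b)
  pj <- tab / sum(tab)
  pa <- rowSums(pj)
  pb <- colSums(pj)
  terms <- pj * log2(pj / outer(pa, pb))
  mi <- sum(terms[pj > 0])
  max(mi, 0)
}

#' Greedy minimum-redundancy maximum-relevance feature selection
#'
#' Selects `n` features from a discretized matrix by the incremental
#' mRMR criterion: the first feature maximizes relevance `I(x; t)` to the
#' label; each subsequent feature maximizes
#' `I(x; t) - mean_(x_j in S) I(x; x_j)` over the unselected candidates,
#' where `S` is the current selection. Ties break by input feature order;
#' scores within `1e-9` bits are treated as tied so that floating-point
#' summation order cannot override the tie rule.
#'
#' @param disc A `discrete_matrix` from [discretize()] (or an integer
#'   matrix, features in rows).
#' @param y Label vector in `{-1, +1}` (used directly as a two-letter
#'   alphabet).
#' @param n Number of features to select (`<=` feature count).
#' @return List of class `mrmr_result`: `selected` (ordered feature IDs),
#'   `step_score` (criterion value at each pick), `relevance` (named
#'   `I(x; t)` for every candidate).
#' @export
mrmr_select <- function(disc, y, n) {
  states <- if (inherits(disc, "discrete_matrix")) disc$states else disc
  stopifnot(ncol(states) == length(y))
  m <- nrow(states)
  if (n > m) stop("n exceeds the number of candidate features")
  relevance <- apply(states, 1, mutual_information, b = y)
  selected <- integer(0)
  step_score <- numeric(0)
  red_sum <- numeric(m)  # sum of I(x; x_j) over selected j
  remaining <- seq_len(m)
  for (step in seq_len(n)) {
    score <- if (length(selected) == 0L) relevance[remaining]
             else relevance[remaining] - red_sum[remaining] / length(selected)
    pos <- which(score >= max(score) - 1e-9)[1L]  # first of the tied maxima
    pick <- remaining[pos]
    step_score <- c(step_score, unname(score[pos]))
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) && step < n) {
      add <- apply(states[remaining, , drop = FALSE], 1,
                   mutual_information, b = states[pick, ])
      red_sum[remaining] <- red_sum[remaining] + add
    }
  }
  structure(list(selected = rownames(states)[selected],
                 step_score = step_score,
                 relevance = stats::setNames(relevance, rownames(states))),
            class = "mrmr_result")
}
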