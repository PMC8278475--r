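# Shared fixture builders for the test suite. Everything is generated in
# code; no binary files.

# Tiny omics matrix with TCGA-style barcodes; values filled by column.
tiny_matrix <- function(values, features, barcodes,
                        feature_type = "protein_coding",
                        data_scale = "counts") {
  m <- matrix(values, nrow = length(features),
              dimnames = list(features, barcodes))
  omics_matrix(m, feature_type = feature_type, data_scale = data_scale)
}

# Write a matrix TSV by hand (independent of write_matrix_tsv).
write_tsv_by_hand <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# Independent quantile-normalization oracle: sort each column, average
# across columns rank-wise, then map each column's values back through the
# rank means (ties get the mean of their rank means).
qn_oracle <- function(x) {
  sorted <- apply(x, 2, sort)
  rank_means <- rowMeans(sorted)
  out <- apply(x, 2, function(col) {
    r <- rank(col, ties.method = "average")
    # non-integer average ranks interpolate between adjacent rank means
    lo <- rank_means[floor(r)]
    hi <- rank_means[ceiling(r)]
    (lo + hi) / 2
  })
  dimnames(out) <- dimnames(x)
  out
}

# Independent plug-in MI oracle: literal double sum over the contingency
# table of the two vectors.
mi_oracle <- function(a, b) {
  n <- length(a)
  av <- unique(a); bv <- unique(b)
  mi <- 0
  for (x in av) for (y in bv) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) {
      px <- sum(a == x) / n
      py <- sum(b == y) / n
      mi <- mi + pxy * log2(pxy / (px * py))
    }
  }
  mi
}

# Independent BH oracle: definitional min-over-tails step-up.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    tail_vals <- vapply(i:m, function(j) p[ord[j]] * m / j, numeric(1))
    q[ord[i]] <- min(1, min(tail_vals))
  }
  q
}

# Independent greedy mRMR oracle recomputing every MI from scratch per step.
mrmr_oracle <- function(states, y, n) {
  ids <- rownames(states)
  selected <- character(0)
  for (step in seq_len(n)) {
    remaining <- setdiff(ids, selected)
    scores <- vapply(remaining, function(f) {
      rel <- mi_oracle(states[f, ], y)
      if (length(selected) == 0) return(rel)
      red <- mean(vapply(selected, function(s)
        mi_oracle(states[f, ], states[s, ]), numeric(1)))
      rel - red
    }, numeric(1))
    selected <- c(selected, remaining[which(scores >= max(scores) - 1e-9)[1]])
  }
  selected
}

# Separable two-block toy learning problem for ensemble tests: feature 1
# separates the classes, the rest are noise. Samples in rows.
separable_xy <- function(n_pos = 12, n_neg = 8, d = 4, seed = 42) {
  set.seed(seed)
  y <- c(rep(1, n_pos), rep(-1, n_neg))
  X <- matrix(rnorm((n_pos + n_neg) * d), n_pos + n_neg, d,
              dimnames = list(NULL, paste0("f", seq_len(d))))
  X[, 1] <- y * 3 + rnorm(n_pos + n_neg, sd = 0.3)
  list(X = X, y = y)
}

# Small synthetic triple dataset for pipeline-level tests (fast).
small_sim <- function(seed = 7L, ...) {
  simulate_triple(synth_spec(
    n_tumor = 30, n_normal = 14, n_pc = 150, n_nc = 80, n_genes_meth = 60,
    d_pc = 12, d_nc = 6, d_meth = 8, seed = seed, ...))
}
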