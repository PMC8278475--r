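test_that("fold plans partition samples with sizes differing by at most one", {
  p <- make_fold_plan(20, F_outer = 10, K_inner = 2, seed = 1)
  expect_equal(as.integer(table(p$outer)), rep(2L, 10))
  p2 <- make_fold_plan(103, F_outer = 10, K_inner = 5, seed = 2)
  sizes <- sort(as.integer(table(p2$outer)))
  expect_equal(sizes, c(rep(10L, 7), rep(11L, 3)))  # pigeonhole
  # partition: every sample in exactly one outer fold
  expect_equal(sort(unique(p2$outer)), 1:10)
  expect_length(p2$outer, 103)
  # inner subsets partition each learning set
  for (f in 1:10) {
    learn <- which(p2$outer != f)
    expect_setequal(as.integer(names(p2$inner[[f]])), learn)
    ks <- table(p2$inner[[f]])
    expect_lte(max(ks) - min(ks), 1)
  }
})

test_that("fold plans are reproducible and stratification keeps ratios", {
  expect_identical(make_fold_plan(50, 5, 3, seed = 14),
                   make_fold_plan(50, 5, 3, seed = 14))
  y <- c(rep(1, 40), rep(-1, 10))
  p <- make_fold_plan(50, F_outer = 5, K_inner = 2, seed = 3,
                      stratify = TRUE, y = y)
  for (f in 1:5)
    expect_equal(sum(y[p$outer == f] == -1), 2L)
  expect_error(make_fold_plan(5, F_outer = 10, K_inner = 2), "more outer folds")
})

test_that("grid tuning returns singletons untouched and picks the winner", {
  sep <- separable_xy()
  spec1 <- base_learner_spec("adaboost")  # singleton grid
  tuned1 <- tune_base_learner(spec1, sep$X, sep$y, inner = rep(1:2, 10))
  expect_equal(tuned1$fitted_params$n_estimators, 50)

  # two-point grid where one gamma is absurd: the sane one wins on
  # separable data
  spec2 <- base_learner_spec("svm_rbf", grid = list(C = 10, gamma = c(0.1, 1e6)))
  inner <- rep_len(1:4, nrow(sep$X))
  tuned2 <- tune_base_learner(spec2, sep$X, sep$y, inner, seed = 5)
  expect_equal(tuned2$fitted_params$gamma, 0.1)
})

test_that("grid winner matches an independent loop-over-grid reference", {
  sep <- separable_xy(n_pos = 16, n_neg = 12, seed = 77)
  grid <- list(C = c(0.1, 1, 10), gamma = 0.5)
  spec <- base_learner_spec("svm_rbf", grid = grid)
  inner <- rep_len(1:3, nrow(sep$X))
  tuned <- tune_base_learner(spec, sep$X, sep$y, inner, seed = 9)
  # reference: explicit loop over grid points and folds
  ref_acc <- vapply(seq_along(grid$C), function(i) {
    mean(vapply(1:3, function(k) {
      tr <- inner != k
      fit <- fit_base_learner(spec, sep$X[tr, ], sep$y[tr],
                              params = list(C = grid$C[i], gamma = 0.5),
                              seed = 9 + i)
      p <- predict_prob(fit, sep$X[!tr, ])
      mean(ifelse(p >= 0.5, 1, -1) == sep$y[!tr])
    }, numeric(1)))
  }, numeric(1))
  expect_equal(tuned$fitted_params$C, grid$C[which.max(ref_acc)])
})

test_that("meta-dataset columns are out-of-fold probabilities plus labels", {
  sep <- separable_xy(n_pos = 6, n_neg = 6, d = 2, seed = 5)
  const_spec <- base_learner_spec("custom",
    fit = function(X, y) "const",
    predict_prob = function(model, X) rep(0.7, nrow(X)))
  inner <- rep_len(1:3, 12)
  meta <- build_meta_dataset(sep$X, sep$y,
                             list(c1 = const_spec, c2 = const_spec),
                             inner, seed = 1)
  expect_equal(meta$c1, rep(0.7, 12))
  expect_equal(meta$c2, rep(0.7, 12))
  expect_equal(meta$label, sep$y)

  # deterministic stub emitting the mean row index of its training set:
  # each held-out row must get the prediction of the model trained on the
  # complement of its own subset
  idx_spec <- base_learner_spec("custom",
    fit = function(X, y) mean(as.numeric(rownames(X))),
    predict_prob = function(model, X) rep(model / 100, nrow(X)))
  rownames(sep$X) <- seq_len(12)
  meta2 <- build_meta_dataset(sep$X, sep$y, list(ix = idx_spec), inner,
                              seed = 1)
  for (k in 1:3) {
    expected <- mean(which(inner != k)) / 100
    expect_equal(unique(meta2$ix[inner == k]), expected)
  }
})

test_that("no meta row is predicted by a model trained on it", {
  sep <- separable_xy(n_pos = 10, n_neg = 8, d = 3, seed = 8)
  n <- nrow(sep$X)
  rownames(sep$X) <- seq_len(n)
  seen <- list()
  spy_spec <- base_learner_spec("custom",
    fit = function(X, y) as.integer(rownames(X)),
    predict_prob = function(model, X) {
      for (r in rownames(X))
        seen[[r]] <<- c(seen[[r]], list(model))
      rep(0.5, nrow(X))
    })
  inner <- unname(make_fold_plan(n, 3, 2, seed = 4)$outer)
  build_meta_dataset(sep$X, sep$y, list(spy = spy_spec), inner, seed = 1)
  for (r in names(seen))
    for (train_rows in seen[[r]])
      expect_false(as.integer(r) %in% train_rows)
})

test_that("leave-one-out stacking trains each model on the other samples", {
  sep <- separable_xy(n_pos = 3, n_neg = 3, d = 2, seed = 10)
  rownames(sep$X) <- 1:6
  sizes <- list()
  spy <- base_learner_spec("custom",
    fit = function(X, y) nrow(X),
    predict_prob = function(model, X) {
      sizes[[length(sizes) + 1L]] <<- model
      rep(0.6, nrow(X))
    })
  build_meta_dataset(sep$X, sep$y, list(s = spy), inner = 1:6, seed = 1)
  expect_true(all(unlist(sizes) == 5L))
})

test_that("meta-learner training behaves on degenerate meta-features", {
  # column 1 equals the label: training accuracy 100%
  set.seed(61)
  y <- rep(c(1, -1), each = 20)
  meta <- data.frame(a = ifelse(y == 1, 1, 0), b = runif(40), label = y)
  fit <- train_meta(meta, grid = 100, seed = 1)
  p <- predict(fit, as.matrix(meta[, c("a", "b")]))
  expect_equal(ifelse(p >= 0.5, 1, -1), y)

  # all-constant columns fall back to the majority class
  meta2 <- data.frame(a = rep(0.5, 30), b = rep(0.5, 30),
                      label = c(rep(1, 20), rep(-1, 10)))
  fit2 <- train_meta(meta2, grid = 50, seed = 1)
  p2 <- predict(fit2, as.matrix(meta2[, c("a", "b")]))
  expect_true(all(p2 >= 0.5))  # majority class is +1

  expect_error(train_meta(data.frame(a = 1:3 / 3, label = c(1, 1, 1))),
               "single-class")
})

test_that("the stacked ensemble separates an easy problem and is deterministic", {
  sep <- separable_xy(n_pos = 18, n_neg = 12, d = 4, seed = 12)
  ens <- train_ensemble(sep$X, sep$y, K = 3, meta_grid = 100, seed = 14)
  test_set <- separable_xy(n_pos = 6, n_neg = 6, d = 4, seed = 99)
  pr <- predict(ens, test_set$X)
  expect_equal(pr$label, test_set$y)        # separable sanity case
  expect_true(all(pr$probability >= 0 & pr$probability <= 1))
  expect_equal(dim(pr$base_probs), c(12L, 4L))

  # a sample identical to a training tumor sample is predicted +1
  pr1 <- predict(ens, sep$X[1, , drop = FALSE])
  expect_equal(pr1$label, 1L)

  ens2 <- train_ensemble(sep$X, sep$y, K = 3, meta_grid = 100, seed = 14)
  pr2 <- predict(ens2, test_set$X)
  expect_identical(pr$probability, pr2$probability)

  expect_error(predict(ens, test_set$X[, 1:2]), "missing selected features")
})

test_that("stacking keeps pace with the best single base learner across seeds", {
  # benchmark conditions (60 tumor / 20 normal, planted |log2FC| = 4,
  # delta-beta = 0.3); identical features and folds for the ensemble and
  # each single classifier
  gaps <- vapply(1:5, function(s) {
    sim <- simulate_triple(synth_spec(seed = 200L + s))
    y <- unname(sim$dataset$y)
    cfg <- pipeline_config(n = 10, seed = s)
    prep <- stackomics:::prepare_blocks(sim$dataset, sim$map, cfg)
    rec <- stackomics:::stage2_select(prep$blocks, y, seq_along(y), cfg)
    cand <- rec$feature_id[rec$selected]
    disc <- discretize(t(prep$X[, cand, drop = FALSE]), k = 0.5)
    feats <- mrmr_select(disc, y, n = min(10, length(cand)))$selected
    X <- prep$X[, feats, drop = FALSE]
    plan <- make_fold_plan(length(y), F_outer = 10, K_inner = 5, seed = s)
    specs <- default_base_learners()
    acc <- matrix(NA_real_, 10, 5,
                  dimnames = list(NULL, c(names(specs), "ensemble")))
    for (f in 1:10) {
      learn <- plan$outer != f
      inner <- unname(plan$inner[[f]])
      for (nm in names(specs)) {
        tuned <- tune_base_learner(specs[[nm]], X[learn, , drop = FALSE],
                                   y[learn], inner, seed = s)
        fit <- fit_base_learner(tuned, X[learn, , drop = FALSE], y[learn],
                                params = tuned$fitted_params, seed = s)
        p <- predict_prob(fit, X[!learn, , drop = FALSE])
        acc[f, nm] <- mean(ifelse(p >= 0.5, 1, -1) == y[!learn])
      }
      ens <- train_ensemble(X[learn, , drop = FALSE], y[learn],
                            inner = inner, meta_grid = 100, seed = s)
      pr <- predict(ens, X[!learn, , drop = FALSE])
      acc[f, "ensemble"] <- mean(pr$label == y[!learn])
    }
    means <- colMeans(acc)
    max(means[names(specs)]) - means[["ensemble"]]
  }, numeric(1))
  expect_true(all(gaps <= 0.02 + 1e-9))
})
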