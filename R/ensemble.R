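#' Build a nested cross-validation fold plan
#'
#' Partitions `n_samples` into `F` outer folds of equal size (sizes differ
#' by at most one) and each outer learning set into `K` inner subsets.
#' Optionally stratified to preserve the class ratio per fold, useful when
#' the normal class is small. Deterministic under `seed`.
#'
#' @param n_samples Number of samples.
#' @param F_outer Number of outer folds (>= 2).
#' @param K_inner Number of inner subsets per learning set (>= 2).
#' @param seed Integer seed.
#' @param stratify Logical; if `TRUE`, `y` must be supplied.
#' @param y Labels, required when `stratify = TRUE`.
#' @return List of class `fold_plan`: `outer` (fold id per sample),
#'   `inner` (per outer fold, subset id per learning-set sample, named by
#'   sample index), `F`, `K`, `seed`.
#' @export
make_fold_plan <- function(n_samples, F_outer = 10, K_inner = 5, seed = 1L,
                           stratify = FALSE, y = NULL) {
  if (F_outer < 2 || K_inner < 2) stop("F_outer and K_inner must be >= 2")
  if (F_outer > n_samples) stop("more outer folds than samples")
  set.seed(seed)
  assign_folds <- function(idx, nf) {
    # shuffled indices dealt into folds; sizes differ by <= 1
    f <- rep_len(seq_len(nf), length(idx))
    stats::setNames(f, sample(idx))
  }
  if (stratify) {
    if (is.null(y) || length(y) != n_samples)
      stop("stratify = TRUE requires labels y")
    outer <- integer(n_samples)
    for (cl in unique(y)) {
      idx <- which(y == cl)
      a <- assign_folds(idx, F_outer)
      outer[as.integer(names(a))] <- a
    }
  } else {
    a <- assign_folds(seq_len(n_samples), F_outer)
    outer <- integer(n_samples)
    outer[as.integer(names(a))] <- a
  }
  inner <- lapply(seq_len(F_outer), function(f) {
    learn <- which(outer != f)
    a <- assign_folds(learn, K_inner)
    k <- integer(length(learn))
    names(k) <- learn[order(learn)]
    k[as.character(as.integer(names(a)))] <- a
    k
  })
  structure(list(outer = outer, inner = inner, F = F_outer, K = K_inner,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Declare a base learner and its tuning grid
#'
#' The four heterogeneous base classifiers and their default grids:
#' RBF-kernel SVM (`C` in \{0.001, 0.01, 0.1\}, `gamma` in
#' \{1, 10, 100\}), decision tree (defaults, no grid), random forest
#' (`n_estimators` in \{50, 100\}), and AdaBoost (`n_estimators = 50`).
#' A `"custom"` kind accepts user `fit(X, y)` / `predict_prob(model, X)`
#' closures (used e.g. to instrument the stacking contract in tests).
#'
#' @param kind One of `"svm_rbf"`, `"decision_tree"`, `"random_forest"`,
#'   `"adaboost"`, `"custom"`.
#' @param grid Named list of parameter value vectors; combinations are
#'   enumerated in declared order for tie-breaking.
#' @param fit,predict_prob Closures for `kind = "custom"`.
#' @return List of class `base_learner_spec`.
#' @export
base_learner_spec <- function(kind = c("svm_rbf", "decision_tree",
                                       "random_forest", "adaboost", "custom"),
                              grid = NULL, fit = NULL, predict_prob = NULL) {
  kind <- match.arg(kind)
  if (is.null(grid))
    grid <- switch(kind,
      svm_rbf = list(C = c(0.001, 0.01, 0.1), gamma = c(1.0, 10.0, 100.0)),
      decision_tree = list(),
      random_forest = list(n_estimators = c(50, 100)),
      adaboost = list(n_estimators = 50),
      custom = list())
  structure(list(kind = kind, grid = grid, fitted_params = NULL,
                 fit = fit, predict_prob = predict_prob),
            class = "base_learner_spec")
}

#' The four default heterogeneous base learners
#'
#' @return Named list of [base_learner_spec()] objects in the order
#'   SVM, decision tree, random forest, AdaBoost.
#' @export
default_base_learners <- function() {
  list(svm_rbf = base_learner_spec("svm_rbf"),
       decision_tree = base_learner_spec("decision_tree"),
       random_forest = base_learner_spec("random_forest"),
       adaboost = base_learner_spec("adaboost"))
}

grid_points <- function(grid) {
  if (length(grid) == 0L) return(list(list()))
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(combos)), function(i) as.list(combos[i, , drop = FALSE]))
}

# AdaBoost (SAMME) with depth-1 rpart stumps; probability of the positive
# class is the alpha-weighted vote share.
fit_adaboost <- function(X, y, n_estimators = 50) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  df <- data.frame(X, .y = factor(y, levels = c(-1, 1)))
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w,
                        method = "class",
                        control = rpart::rpart.control(maxdepth = 1,
                                                       cp = -1, minsplit = 2,
                                                       xval = 0))
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    err <- sum(w * (pred != y))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    if (alpha <= 0) break
    w <- w * exp(-alpha * y * pred)
    w <- w / sum(w)
    stumps[[m]] <- fit
    alphas[m] <- alpha
    if (err < 1e-9) break
  }
  structure(list(stumps = stumps, alphas = alphas,
                 feature_names = colnames(X)),
            class = "adaboost_fit")
}

predict_adaboost_prob <- function(model, X) {
  df <- as.data.frame(X)
  votes <- vapply(seq_along(model$stumps), function(m) {
    pred <- as.integer(as.character(predict(model$stumps[[m]], df,
                                            type = "class")))
    model$alphas[m] * (pred == 1L)
  }, numeric(nrow(df)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = nrow(df))
  rowSums(votes) / sum(model$alphas)
}

#' Fit one base learner with given parameters
#'
#' @param spec A [base_learner_spec()].
#' @param X Sample-by-feature numeric matrix.
#' @param y Labels in `{-1, +1}`.
#' @param params Named list of parameter values (one grid point).
#' @param seed Seed set before fitting (SVM probability calibration and
#'   random forests consume RNG).
#' @return Fitted model of class `base_learner_fit`.
#' @export
fit_base_learner <- function(spec, X, y, params = list(), seed = 1L) {
  set.seed(seed)
  yf <- factor(y, levels = c(-1, 1))
  model <- switch(spec$kind,
    svm_rbf = e1071::svm(X, yf, kernel = "radial",
                         cost = params$C %||% 1,
                         gamma = params$gamma %||% (1 / ncol(X)),
                         probability = TRUE, scale = FALSE),
    decision_tree = rpart::rpart(.y ~ ., data = data.frame(X, .y = yf),
                                 method = "class"),
    random_forest = randomForest::randomForest(
      X, yf, ntree = params$n_estimators %||% 500),
    adaboost = fit_adaboost(X, y, params$n_estimators %||% 50),
    custom = spec$fit(X, y))
  structure(list(kind = spec$kind, model = model, params = params,
                 spec = spec),
            class = "base_learner_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Positive-class probability from a fitted base learner
#'
#' @param fit A `base_learner_fit`.
#' @param X Sample-by-feature matrix.
#' @return Numeric vector of P(tumor) in \[0, 1\].
#' @export
predict_prob <- function(fit, X) {
  switch(fit$kind,
    svm_rbf = {
      pr <- attr(predict(fit$model, X, probability = TRUE), "probabilities")
      unname(pr[, "1"])
    },
    decision_tree = unname(predict(fit$model, as.data.frame(X),
                                   type = "prob")[, "1"]),
    random_forest = unname(predict(fit$model, X, type = "prob")[, "1"]),
    adaboost = predict_adaboost_prob(fit$model, X),
    custom = fit$spec$predict_prob(fit$model, X))
}

#' Tune a base learner by inner cross-validation accuracy
#'
#' Scores every grid point by its mean accuracy over the inner validating
#' subsets (train on the other `K - 1` subsets, evaluate on the held-out
#' one) and returns the winner; ties go to the first point in declared
#' grid order. A singleton (or empty) grid is returned without any CV.
#' A grid point whose fit fails scores 0 with a warning.
#'
#' @param spec A [base_learner_spec()].
#' @param X,y Learning-set features (samples in rows) and labels.
#' @param inner Inner subset assignment for the learning-set rows
#'   (integer vector over `1..K`).
#' @param seed Seed for the fits.
#' @return `spec` with `fitted_params` set.
#' @export
tune_base_learner <- function(spec, X, y, inner, seed = 1L) {
  pts <- grid_points(spec$grid)
  if (length(pts) == 1L) {
    spec$fitted_params <- pts[[1L]]
    return(spec)
  }
  acc <- vapply(seq_along(pts), function(i) {
    fold_acc <- vapply(sort(unique(inner)), function(k) {
      tr <- inner != k
      fit <- tryCatch(
        fit_base_learner(spec, X[tr, , drop = FALSE], y[tr],
                         params = pts[[i]], seed = seed + i),
        error = function(e) NULL)
      if (is.null(fit)) {
        warning("grid point ", i, " failed to fit; scored 0")
        return(0)
      }
      p <- predict_prob(fit, X[!tr, , drop = FALSE])
      mean(ifelse(p >= 0.5, 1, -1) == y[!tr])
    }, numeric(1))
    mean(fold_acc)
  }, numeric(1))
  spec$fitted_params <- pts[[which.max(acc)]]
  spec
}

#' Build the second-learning meta-dataset of out-of-fold probabilities
#'
#' For each inner subset `k`, every tuned base learner is trained on the
#' other `K - 1` subsets and predicts class probabilities on subset `k`;
#' stacking all `K` held-out predictions yields one row per learning-set
#' sample: four positive-class probabilities joined with the true label.
#' No row is ever predicted by a model trained on it, so the base
#' learners' probability errors are embedded in the new dataset.
#'
#' @param X,y Learning-set features and labels.
#' @param specs List of tuned [base_learner_spec()]s (with `fitted_params`).
#' @param inner Inner subset assignment over the learning-set rows.
#' @param seed Seed for the fits.
#' @return Data frame with one probability column per learner plus `label`;
#'   rows in learning-set order.
#' @export
build_meta_dataset <- function(X, y, specs, inner, seed = 1L) {
  n <- nrow(X)
  probs <- matrix(NA_real_, n, length(specs),
                  dimnames = list(rownames(X), names(specs)))
  for (k in sort(unique(inner))) {
    tr <- inner != k
    for (j in seq_along(specs)) {
      fit <- fit_base_learner(specs[[j]], X[tr, , drop = FALSE], y[tr],
                              params = specs[[j]]$fitted_params,
                              seed = seed + 31L * j + k)
      probs[!tr, j] <- predict_prob(fit, X[!tr, , drop = FALSE])
    }
  }
  if (anyNA(probs)) stop("inner subsets do not cover the learning set")
  out <- as.data.frame(probs)
  out$label <- y
  out
}

#' Train the gradient-boosted meta-learner on the meta-dataset
#'
#' Fits a gradient-boosted tree classifier (binary logistic objective) on
#' the base-learner probability columns; each boosting round fits the
#' residual between the true and currently predicted value, so the
#' learner corrects the base classifiers' probability errors. Because the
#' meta problem has only one probability column per base learner, trees
#' are kept shallow (`max_depth = 2`) and each round samples a single
#' column (`colsample_bytree = 0.25` with the four default learners):
#' boosting then spreads its weight over all base classifiers rather than
#' locking onto one column that happens to separate the out-of-fold data,
#' which keeps the ensemble robust when a single base learner misfires on
#' a new sample. The number of rounds is chosen from `grid` by inner CV
#' accuracy on the meta-dataset; ties go to the first grid value.
#'
#' @param meta Data frame from [build_meta_dataset()].
#' @param grid Candidate `n_estimators` (boosting rounds), default
#'   `c(100, 200, 300)`.
#' @param K_inner Folds for the rounds selection (default 5, reduced if
#'   the meta-dataset is small).
#' @param seed Seed.
#' @return Fitted `xgb.Booster` with attribute `n_estimators`.
#' @export
train_meta <- function(meta, grid = c(100, 200, 300), K_inner = 5,
                       seed = 1L) {
  feat <- as.matrix(meta[, setdiff(names(meta), "label"), drop = FALSE])
  y01 <- ifelse(meta$label == 1, 1, 0)
  if (length(unique(y01)) < 2L) stop("meta-dataset labels are single-class")
  xgb_fit <- function(X, y, nrounds) {
    dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
    xgboost::xgb.train(params = list(objective = "binary:logistic",
                                     nthread = 1, seed = seed,
                                     max_depth = 2,
                                     colsample_bytree = 1 / ncol(X)),
                       data = dtrain, nrounds = nrounds, verbose = 0)
  }
  best <- grid[1L]
  if (length(grid) > 1L) {
    set.seed(seed)
    K <- min(K_inner, floor(nrow(feat) / 2))
    folds <- rep_len(seq_len(K), nrow(feat))[sample(nrow(feat))]
    acc <- vapply(grid, function(nr) {
      mean(vapply(seq_len(K), function(k) {
        tr <- folds != k
        set.seed(seed + nr + k)
        fit <- xgb_fit(feat[tr, , drop = FALSE], y01[tr], nr)
        p <- predict(fit, feat[!tr, , drop = FALSE])
        mean((p >= 0.5) == (y01[!tr] == 1))
      }, numeric(1)))
    }, numeric(1))
    best <- grid[which.max(acc)]
  }
  set.seed(seed)
  fit <- xgb_fit(feat, y01, best)
  attr(fit, "n_estimators") <- best
  fit
}

#' Train the full stacked ensemble on a learning set
#'
#' Runs the complete second-learning procedure on one learning set:
#' tunes each base learner by inner-CV grid search, builds the
#' out-of-fold probability meta-dataset, fits the boosted-tree
#' meta-learner on it, and finally retrains the four base learners on the
#' whole learning set with their tuned parameters (these produce the
#' meta-features for new samples).
#'
#' @param X,y Learning-set features (samples in rows; columns are the
#'   selected features) and labels in `{-1, +1}`.
#' @param specs Base learner specs, default [default_base_learners()].
#' @param inner Inner subset assignment (from [make_fold_plan()]); if
#'   `NULL`, a `K`-fold assignment is drawn under `seed`.
#' @param K Inner fold count used when `inner` is `NULL`.
#' @param meta_grid Boosting-round grid for the meta-learner.
#' @param threshold Decision threshold on the meta probability.
#' @param seed Seed.
#' @return Object of class `stacked_ensemble`.
#' @export
train_ensemble <- function(X, y, specs = default_base_learners(),
                           inner = NULL, K = 5,
                           meta_grid = c(100, 200, 300),
                           threshold = 0.5, seed = 1L) {
  stopifnot(nrow(X) == length(y), all(y %in% c(-1, 1)))
  if (is.null(inner)) {
    set.seed(seed)
    inner <- rep_len(seq_len(min(K, nrow(X))), nrow(X))[sample(nrow(X))]
  }
  tuned <- lapply(seq_along(specs), function(j)
    tune_base_learner(specs[[j]], X, y, inner, seed = seed + 97L * j))
  names(tuned) <- names(specs)
  meta <- build_meta_dataset(X, y, tuned, inner, seed = seed)
  meta_fit <- train_meta(meta, grid = meta_grid, seed = seed)
  base_fits <- lapply(seq_along(tuned), function(j)
    fit_base_learner(tuned[[j]], X, y, params = tuned[[j]]$fitted_params,
                     seed = seed + 7L * j))
  names(base_fits) <- names(tuned)
  structure(list(features = colnames(X), base_fits = base_fits,
                 meta_fit = meta_fit, meta = meta,
                 tuned_params = lapply(tuned, `[[`, "fitted_params"),
                 threshold = threshold, seed = seed),
            class = "stacked_ensemble")
}

#' Predict labels and probabilities with a stacked ensemble
#'
#' @param object A `stacked_ensemble`.
#' @param newdata Sample-by-feature matrix carrying all selected features.
#' @param ... Unused.
#' @return List with `label` (`{-1, +1}`), `probability` (meta P(tumor)),
#'   and `base_probs` (matrix of the four base probabilities).
#' @export
predict.stacked_ensemble <- function(object, newdata, ...) {
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing))
    stop("missing selected features: ", paste(missing, collapse = ", "))
  newdata <- newdata[, object$features, drop = FALSE]
  base_probs <- vapply(object$base_fits,
                       function(f) predict_prob(f, newdata),
                       numeric(nrow(newdata)))
  if (is.null(dim(base_probs)))
    base_probs <- matrix(base_probs, nrow = nrow(newdata),
                         dimnames = list(NULL, names(object$base_fits)))
  p <- predict(object$meta_fit, base_probs)
  list(label = ifelse(p >= object$threshold, 1L, -1L), probability = p,
       base_probs = base_probs)
}
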