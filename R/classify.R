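#' Drop near-empty features
#'
#' Removes feature columns whose fraction of missing values among training
#' rows exceeds `threshold`. With `drop_list` a fixed list of feature names
#' is removed instead (the published study dropped L_AMP_Q, L_AMP_S,
#' C_AMP_P, C_AMP_Q, C_AMP_S and C_T_PR, leaving 50 features; pass
#' `drop_list = published_drop_list()` to reproduce that).
#'
#' @param data tibble with feature columns plus `id`, `label` and
#'   optionally `set` (train/test mask; missingness is then assessed on
#'   training rows only).
#' @param threshold missing-fraction threshold (default 0.90).
#' @param drop_list optional fixed character vector of features to drop.
#' @return The table without the dropped feature columns.
#' @export
drop_sparse_features <- function(data, threshold = 0.90, drop_list = NULL) {
  meta <- intersect(c("id", "label", "set"), names(data))
  feats <- setdiff(names(data), meta)
  if (!is.null(drop_list)) {
    return(dplyr::select(data, -dplyr::any_of(drop_list)))
  }
  rows <- if ("set" %in% names(data)) data$set == "train" else rep(TRUE, nrow(data))
  frac <- vapply(feats, function(f) mean(is.na(data[[f]][rows])), numeric(1))
  dplyr::select(data, -dplyr::all_of(feats[frac > threshold]))
}

#' @rdname drop_sparse_features
#' @export
published_drop_list <- function() {
  c("L_AMP_Q", "L_AMP_S", "C_AMP_P", "C_AMP_Q", "C_AMP_S", "C_T_PR")
}

#' Stratified train/test split
#'
#' Adds a `set` column ("train"/"test") by label-stratified sampling.
#'
#' @param data tibble with a `label` column.
#' @param prop training fraction (default 0.8).
#' @param seed integer seed.
#' @return The table with a `set` column.
#' @export
split_train_test <- function(data, prop = 0.8, seed = 1) {
  set.seed(seed)
  set <- rep("test", nrow(data))
  for (lv in unique(data$label)) {
    idx <- which(data$label == lv)
    n_tr <- round(prop * length(idx))
    set[sample(idx, n_tr)] <- "train"
  }
  data$set <- set
  data
}

#' Median imputation and z-score normalisation without test leakage
#'
#' Per-feature medians, means and SDs are computed on training rows only
#' and applied to both sets. Constant features pass through unscaled (and
#' are recorded in the `constant` attribute).
#'
#' @param data tibble with feature columns and a `set` column.
#' @return The table with imputed, scaled features.
#' @export
impute_and_scale <- function(data) {
  stopifnot("set" %in% names(data))
  meta <- intersect(c("id", "label", "set"), names(data))
  feats <- setdiff(names(data), meta)
  tr <- data$set == "train"
  constant <- character(0)
  for (f in feats) {
    v <- data[[f]]
    med <- stats::median(v[tr], na.rm = TRUE)
    if (is.na(med)) med <- 0
    v[is.na(v)] <- med
    mu <- mean(v[tr])
    s <- stats::sd(v[tr])
    if (is.na(s) || s == 0) {
      constant <- c(constant, f)
    } else {
      v <- (v - mu) / s
    }
    data[[f]] <- v
  }
  attr(data, "constant") <- constant
  data
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of scores against binary labels, with
#' midranks for ties.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (0/1).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-index decision threshold
#'
#' Scans all midpoints between consecutive sorted unique scores and returns
#' the one maximising sensitivity + specificity - 1 (a sample is called
#' positive when its score is >= the threshold). Ties are broken toward the
#' higher threshold, i.e. toward higher specificity. With a single unique
#' score the Youden index is 0 at any threshold and that score is returned.
#'
#' @param scores numeric training scores.
#' @param labels binary labels (0/1).
#' @return The threshold.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  u <- sort(unique(scores))
  if (length(u) == 1) return(u)
  cand <- (u[-1] + u[-length(u)]) / 2
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  j <- vapply(cand, function(th) {
    sens <- sum(scores >= th & labels == 1) / n1
    spec <- sum(scores < th & labels == 0) / n0
    sens + spec - 1
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)
  cand[max(best)]
}

#' Classification metrics on a test set
#'
#' AUC from the score ranking plus thresholded confusion-matrix metrics.
#'
#' @param scores numeric test scores.
#' @param labels binary labels (0/1).
#' @param threshold decision threshold (chosen on training data).
#' @param model model name to record.
#' @return One-row tibble: model, auc, accuracy, sensitivity, specificity,
#'   precision, f1, threshold, plus the confusion counts.
#' @export
evaluate_scores <- function(scores, labels, threshold, model = "model") {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  tibble::tibble(model = model, auc = auc_score(scores, labels),
                 accuracy = (tp + tn) / length(labels),
                 sensitivity = sens, specificity = spec, precision = prec,
                 f1 = f1, threshold = threshold,
                 tp = tp, fp = fp, tn = tn, fn = fn)
}

# ---- model backends ---------------------------------------------------

# Averaged perceptron with optional L2 weight decay on updates. Labels in
# {0,1}; decision-function scores (no probabilities).
perceptron_fit <- function(X, y, penalty = "none", alpha = 1e-4,
                           epochs = 50, seed = 1) {
  y2 <- ifelse(y == 1, 1, -1)
  p <- ncol(X)
  w <- numeric(p); b <- 0
  wsum <- numeric(p); bsum <- 0; cnt <- 0
  set.seed(seed)
  for (e in seq_len(epochs)) {
    for (i in sample(nrow(X))) {
      if (y2[i] * (sum(w * X[i, ]) + b) <= 0) {
        if (penalty == "l2") w <- (1 - alpha) * w
        w <- w + y2[i] * X[i, ]
        b <- b + y2[i]
      }
      wsum <- wsum + w; bsum <- bsum + b; cnt <- cnt + 1
    }
  }
  list(w = wsum / cnt, b = bsum / cnt)
}

perceptron_score <- function(fit, X) as.numeric(X %*% fit$w + fit$b)

# Default hyperparameter grids (the published text does not state grids;
# these are conventional small grids).
default_grids <- function() {
  list(
    svm_rbf = expand.grid(cost = c(0.1, 1, 10),
                          gamma = c(NA, 0.01, 0.1)),
    perceptron = data.frame(penalty = c("none", "l2", "l2"),
                            alpha = c(1e-4, 1e-4, 1e-3),
                            stringsAsFactors = FALSE),
    random_forest = expand.grid(ntree = c(100, 300),
                                depth = c(NA, 5, 10)),
    xgboost = expand.grid(max_depth = c(2, 4, 6),
                          eta = c(0.05, 0.1, 0.3),
                          nrounds = c(100, 300))
  )
}

fit_one <- function(name, X, y, params, seed) {
  set.seed(seed)
  fit <- switch(
    name,
    svm_rbf = {
      g <- if (is.na(params$gamma)) 1 / ncol(X) else params$gamma
      # inputs are already z-scored upstream; scale = FALSE also keeps
      # constant (unscalable) columns from erroring
      e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial",
                 cost = params$cost, gamma = g, probability = TRUE,
                 scale = FALSE)
    },
    perceptron = perceptron_fit(X, y, params$penalty, params$alpha,
                                seed = seed),
    random_forest = {
      mx <- if (is.na(params$depth)) NULL else {
        min(2^params$depth, max(2, nrow(X) - 1))
      }
      randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                 ntree = params$ntree, maxnodes = mx)
    },
    xgboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth, eta = params$eta,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
      nrounds = params$nrounds, verbose = 0),
    stop("unknown model: ", name)
  )
  list(name = name, fit = fit, params = params)
}

score_model <- function(model, X) {
  switch(
    model$name,
    svm_rbf = {
      if (is.null(rownames(X))) rownames(X) <- seq_len(nrow(X))
      pr <- predict(model$fit, X, probability = TRUE)
      unname(attr(pr, "probabilities")[, "1"])
    },
    perceptron = perceptron_score(model$fit, X),
    random_forest = predict(model$fit, X, type = "prob")[, "1"],
    xgboost = predict(model$fit, X)
  )
}

# Stratified k-fold assignment.
make_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (lv in unique(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

# Grid search one model family by mean CV AUC.
grid_search <- function(name, X, y, grid, cv = 10, seed = 1) {
  k <- min(cv, min(table(y)))
  fold <- make_folds(y, k, seed)
  cv_auc <- vapply(seq_len(nrow(grid)), function(g) {
    aucs <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      m <- fit_one(name, X[tr, , drop = FALSE], y[tr], grid[g, , drop = FALSE],
                   seed + 1000 * g + f)
      sc <- score_model(m, X[!tr, , drop = FALSE])
      if (length(unique(y[!tr])) < 2) return(NA_real_)
      auc_score(sc, y[!tr])
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(cv_auc)
  list(params = grid[best, , drop = FALSE], cv_auc = cv_auc[best],
       folds = k)
}

#' Fit the classifier suite with cross-validated grid search
#'
#' For each requested model family, hyperparameters are chosen by mean AUC
#' over stratified 10-fold cross-validation on the training rows (fold
#' count reduced when a class is smaller than the fold count), then the
#' model is refit on all training rows. Deterministic under `seed`.
#'
#' @param data preprocessed table (see [impute_and_scale()]) with `set`.
#' @param models character vector among `"svm_rbf"`, `"perceptron"`,
#'   `"random_forest"`, `"xgboost"`.
#' @param cv fold count (default 10).
#' @param seed integer seed.
#' @param grids named list of hyperparameter grids (defaults from
#'   `default_grids()`).
#' @return Named list of fitted models with chosen parameters and training
#'   Youden thresholds.
#' @export
fit_models <- function(data, models = c("svm_rbf", "perceptron",
                                        "random_forest", "xgboost"),
                       cv = 10, seed = 1, grids = default_grids()) {
  tr <- data$set == "train"
  y <- as.integer(data$label[tr])
  if (length(unique(y)) < 2) stop("training data has a single class")
  feats <- setdiff(names(data), c("id", "label", "set"))
  X <- as.matrix(data[tr, feats])
  out <- list()
  for (nm in models) {
    gs <- grid_search(nm, X, y, grids[[nm]], cv = cv, seed = seed)
    m <- fit_one(nm, X, y, gs$params, seed)
    tr_scores <- score_model(m, X)
    m$cv_auc <- gs$cv_auc
    m$folds <- gs$folds
    m$threshold <- youden_threshold(tr_scores, y)
    m$features <- feats
    out[[nm]] <- m
  }
  out
}

#' Evaluate fitted models on the held-out test rows
#'
#' @param models list from [fit_models()].
#' @param data the same preprocessed table.
#' @return Tibble of per-model test metrics (see [evaluate_scores()]).
#' @export
evaluate_models <- function(models, data) {
  te <- data$set == "test"
  y <- as.integer(data$label[te])
  rows <- purrr::map(models, function(m) {
    X <- as.matrix(data[te, m$features])
    sc <- score_model(m, X)
    rep <- evaluate_scores(sc, y, m$threshold, model = m$name)
    rep$cv_auc <- m$cv_auc
    rep
  })
  dplyr::bind_rows(rows)
}
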