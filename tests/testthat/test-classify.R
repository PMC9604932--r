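fake_table <- function(n = 40, p = 5, seed = 1, effect = 1) {
  set.seed(seed)
  label <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1] <- X[, 1] + effect * label
  tbl <- tibble::as_tibble(as.data.frame(X))
  names(tbl) <- paste0("f", seq_len(p))
  dplyr::bind_cols(tibble::tibble(id = as.character(seq_len(n)),
                                  label = label), tbl)
}

test_that("sparse features are dropped against training rows only", {
  tbl <- fake_table(40)
  tbl$f5[1:38] <- NA  # 95% missing
  out <- drop_sparse_features(tbl)
  expect_false("f5" %in% names(out))
  expect_true(all(paste0("f", 1:4) %in% names(out)))
  expect_identical(names(drop_sparse_features(fake_table(20))),
                   names(fake_table(20)))
})

test_that("the published drop list leaves 50 of the 56 features", {
  full <- tibble::as_tibble(as.list(stats::setNames(rnorm(56),
                                                    feature_names_56())))
  full <- dplyr::bind_cols(tibble::tibble(id = "a", label = 0L), full)
  out <- drop_sparse_features(full, drop_list = published_drop_list())
  expect_equal(ncol(out) - 2, 50)
})

test_that("imputation and scaling use training statistics only", {
  tbl <- tibble::tibble(id = as.character(1:6), label = c(0L,1L,0L,1L,0L,1L),
                        set = c(rep("train", 3), rep("test", 3)),
                        f1 = c(1, 2, 100, NA, 5, 6),
                        f2 = c(1, 1, 1, 9, 9, 9))
  out <- impute_and_scale(tbl)
  # test-row NA imputed with the training median (2)
  expect_equal(out$f1[4], (2 - mean(c(1, 2, 100))) / sd(c(1, 2, 100)))
  tr <- out$set == "train"
  expect_equal(mean(out$f1[tr]), 0, tolerance = 1e-12)
  expect_equal(sd(out$f1[tr]), 1, tolerance = 1e-12)
  # test columns are generally not standardised
  expect_gt(abs(mean(out$f2[!tr])), 0.5)
  # constant-on-train features pass through
  expect_equal(out$f2[tr], c(1, 1, 1))
  expect_true("f2" %in% attr(out, "constant"))
})

test_that("AUC equals brute-force pair counting and is rank invariant", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(10:40, 1)
    scores <- round(rnorm(n), 1)  # induce ties
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(auc_score(scores, labels), oracle_auc(scores, labels))
    expect_equal(auc_score(exp(3 * scores), labels),
                 auc_score(scores, labels))
  }
})

test_that("the Youden threshold matches exhaustive search", {
  expect_equal(youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 0.5)
  expect_equal(youden_threshold(rep(0.4, 6), c(0, 1, 0, 1, 0, 1)), 0.4)
  for (s in 1:25) {
    set.seed(100 + s)
    n <- sample(10:50, 1)
    scores <- round(runif(n), 2)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(youden_threshold(scores, labels),
                 oracle_youden(scores, labels), info = paste("seed", s))
  }
})

test_that("evaluation metrics follow the confusion matrix", {
  r <- evaluate_scores(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), 0.5)
  expect_equal(r$auc, 1)
  expect_equal(r$accuracy, 1)
  expect_equal(r$f1, 1)
  # TP=5 FP=5 TN=5 FN=5
  scores <- c(rep(0.9, 5), rep(0.1, 5), rep(0.9, 5), rep(0.1, 5))
  labels <- c(rep(1, 5), rep(1, 5), rep(0, 5), rep(0, 5))
  r2 <- evaluate_scores(scores, labels, 0.5)
  expect_equal(r2$accuracy, 0.5)
  expect_equal(r2$precision, 0.5)
  expect_equal(r2$f1, 0.5)
})

test_that("all four model families separate a linearly separable table", {
  tbl <- fake_table(60, effect = 6)
  tbl <- split_train_test(tbl, seed = 2)
  tbl <- impute_and_scale(tbl)
  fits <- fit_models(tbl, cv = 5, seed = 2)
  tr <- tbl$set == "train"
  y <- tbl$label[tr]
  for (m in fits) {
    sc <- pwaveiso:::score_model(m, as.matrix(tbl[tr, m$features]))
    expect_equal(auc_score(sc, y), 1, tolerance = 0.01)
  }
})

test_that("model selection is deterministic under seed", {
  tbl <- fake_table(40, effect = 1)
  tbl <- split_train_test(tbl, seed = 3)
  tbl <- impute_and_scale(tbl)
  f1 <- fit_models(tbl, models = c("xgboost", "perceptron"), cv = 4, seed = 9)
  f2 <- fit_models(tbl, models = c("xgboost", "perceptron"), cv = 4, seed = 9)
  expect_identical(f1$xgboost$params, f2$xgboost$params)
  expect_identical(f1$perceptron$params, f2$perceptron$params)
  expect_equal(f1$perceptron$fit$w, f2$perceptron$fit$w)
})

test_that("permuted labels give chance-level cross-validated AUC", {
  set.seed(11)
  tbl <- fake_table(200, p = 6, effect = 2)
  tbl$label <- sample(tbl$label)  # break the association
  tbl <- split_train_test(tbl, seed = 11)
  tbl <- impute_and_scale(tbl)
  feats <- paste0("f", 1:6)
  tr <- tbl$set == "train"
  X <- as.matrix(tbl[tr, feats]); y <- tbl$label[tr]
  fold <- pwaveiso:::make_folds(y, 5, seed = 11)
  for (nm in c("svm_rbf", "random_forest", "xgboost", "perceptron")) {
    par <- pwaveiso:::default_grids()[[nm]][1, , drop = FALSE]
    aucs <- vapply(1:5, function(f) {
      m <- pwaveiso:::fit_one(nm, X[fold != f, ], y[fold != f], par, seed = f)
      auc_score(pwaveiso:::score_model(m, X[fold == f, , drop = FALSE]),
                y[fold == f])
    }, numeric(1))
    expect_equal(mean(aucs), 0.5, tolerance = 0.2)
  }
})

test_that("no test-set statistics leak into preprocessing", {
  tbl <- fake_table(40)
  tbl$f2[c(3, 25)] <- NA
  tbl <- split_train_test(tbl, seed = 5)
  full <- impute_and_scale(tbl)
  train_only <- impute_and_scale(dplyr::filter(tbl, set == "train"))
  tr_rows <- which(tbl$set == "train")
  expect_equal(as.data.frame(full[tr_rows, paste0("f", 1:5)]),
               as.data.frame(train_only[, paste0("f", 1:5)]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Shapley importance ignores null features and is locally accurate", {
  set.seed(21)
  n <- 80
  X <- matrix(rnorm(n * 3), n, 3)
  w <- c(2, 1, 0)
  y <- as.integer((X %*% w + rnorm(n, 0, 0.1)) > 0)
  tbl <- dplyr::bind_cols(tibble::tibble(id = as.character(1:n), label = y),
                          tibble::as_tibble(as.data.frame(X)))
  names(tbl)[3:5] <- c("f1", "f2", "f3")
  tbl <- split_train_test(tbl, seed = 21)
  tbl <- impute_and_scale(tbl)
  fits <- fit_models(tbl, models = "perceptron", cv = 4, seed = 21)
  imp <- shap_importance(fits$perceptron, tbl, n_perm = 20, seed = 3)
  v <- stats::setNames(imp$importance, imp$feature)
  expect_lt(v["f3"], 0.05 * max(v))
  # linear model: importance ratio tracks |w1| : |w2| on standardised inputs
  expect_equal(unname(v["f1"] / v["f2"]), 2, tolerance = 0.3)
  # local accuracy: per-row values sum to f(x) - baseline
  phi <- attr(imp, "shap_values")
  te <- tbl$set == "test"
  fx <- pwaveiso:::score_model(fits$perceptron,
                               as.matrix(tbl[te, fits$perceptron$features]))
  fx <- fx[seq_len(nrow(phi))]
  expect_lt(max(abs(rowSums(phi) - (fx - attr(imp, "baseline")))), 1e-2)
})
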