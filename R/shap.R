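#' Sampling-based Shapley feature importance
#'
#' Model-agnostic permutation estimate of Shapley values. For each sampled
#' feature permutation a background row is drawn; features are switched
#' from the background value to the evaluation row's value in permutation
#' order and the score change at each switch is credited to that feature.
#' By telescoping, the per-row Shapley values sum exactly to
#' `f(x) - mean(f(background draws))` (the local-accuracy property).
#' Global importance is the mean absolute Shapley value per feature across
#' the evaluation rows.
#'
#' @param model a fitted model from [fit_models()].
#' @param data preprocessed table with `set` column.
#' @param n_eval max evaluation rows (taken from the test rows, or train
#'   if no test rows; default 40).
#' @param n_background background rows sampled from training rows
#'   (default 50).
#' @param n_perm permutations sampled (default 10).
#' @param seed integer seed.
#' @return An `importance_report`: tibble `feature`, `importance`, `rank`,
#'   with the per-row Shapley matrix in the `shap_values` attribute and the
#'   background mean prediction in `baseline`.
#' @export
shap_importance <- function(model, data, n_eval = 40, n_background = 50,
                            n_perm = 10, seed = 1) {
  feats <- model$features
  p <- length(feats)
  te <- if (any(data$set == "test")) data$set == "test" else data$set == "train"
  X_eval <- as.matrix(data[te, feats])
  if (nrow(X_eval) > n_eval) X_eval <- X_eval[seq_len(n_eval), , drop = FALSE]
  X_bg <- as.matrix(data[data$set == "train", feats])
  set.seed(seed)
  if (nrow(X_bg) > n_background) {
    X_bg <- X_bg[sample(nrow(X_bg), n_background), , drop = FALSE]
  }
  ne <- nrow(X_eval)
  phi <- matrix(0, ne, p, dimnames = list(NULL, feats))
  bg_pred <- 0
  for (r in seq_len(n_perm)) {
    perm <- sample(p)
    b <- X_bg[((r - 1) %% nrow(X_bg)) + 1, ]
    # rows: for each eval row, p+1 coalitions from all-background to all-x
    big <- matrix(rep(b, each = (p + 1) * ne), (p + 1) * ne, p)
    colnames(big) <- feats
    for (j in seq_len(p)) {
      fidx <- perm[seq_len(j)]
      rows <- (j * ne + 1):((j + 1) * ne)  # coalition of size j
      big[rows, ] <- matrix(rep(b, each = ne), ne, p)
      big[rows, fidx] <- X_eval[, fidx, drop = FALSE]
    }
    sc <- score_model(model, big)
    scm <- matrix(sc, ne, p + 1)  # column j+1 = coalition size j
    bg_pred <- bg_pred + mean(scm[, 1]) / n_perm
    for (j in seq_len(p)) {
      phi[, perm[j]] <- phi[, perm[j]] + (scm[, j + 1] - scm[, j]) / n_perm
    }
  }
  imp <- colMeans(abs(phi))
  out <- tibble::tibble(feature = feats, importance = as.numeric(imp))
  out <- dplyr::arrange(out, dplyr::desc(.data$importance))
  out$rank <- seq_len(nrow(out))
  attr(out, "shap_values") <- phi
  attr(out, "baseline") <- bg_pred
  class(out) <- c("importance_report", class(out))
  out
}
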