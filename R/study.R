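#' Run the full classification study on a feature table
#'
#' The complete ML stage: stratified 80/20 split, sparse-feature dropping,
#' training-only median imputation and z-scoring, grid-searched fitting of
#' the four classifier families under stratified cross-validation,
#' Youden-index thresholding on the training scores, held-out evaluation,
#' and Shapley importance for the model with the best test AUC. Optionally
#' the same pipeline is run on the two-feature reduction (P amplitude on
#' the limb lead + P duration) for comparison.
#'
#' @param features tibble from [cohort_features()] (`id`, `label`, 56
#'   feature columns).
#' @param prop training fraction (default 0.8).
#' @param seed integer seed; determines split, folds and fits.
#' @param models model families, see [fit_models()].
#' @param cv fold count (default 10).
#' @param two_feature also run the P-amplitude + P-duration model
#'   (default `TRUE`).
#' @param shap compute Shapley importance for the best model
#'   (default `TRUE`).
#' @param drop_threshold missing-fraction threshold for feature dropping.
#' @return An `af_study` object with `reports` (per-model metrics),
#'   `two_feature_reports`, `importance`, `data` (the processed table) and
#'   the fitted `models`.
#' @export
run_study <- function(features, prop = 0.8, seed = 1,
                      models = c("svm_rbf", "perceptron", "random_forest",
                                 "xgboost"),
                      cv = 10, two_feature = TRUE, shap = TRUE,
                      drop_threshold = 0.90) {
  stopifnot(all(c("id", "label") %in% names(features)))
  run_once <- function(tbl) {
    tbl <- split_train_test(tbl, prop = prop, seed = seed)
    if (!any(tbl$set == "test")) {
      stop("holdout test set is empty; lower `prop` or provide more records")
    }
    tbl <- drop_sparse_features(tbl, threshold = drop_threshold)
    tbl <- impute_and_scale(tbl)
    fits <- fit_models(tbl, models = models, cv = cv, seed = seed)
    list(data = tbl, models = fits, reports = evaluate_models(fits, tbl))
  }
  full <- run_once(features)
  two <- NULL
  if (two_feature) {
    keep <- intersect(c("id", "label", "P_dur", "L_AMP_P"), names(features))
    two <- run_once(dplyr::select(features, dplyr::all_of(keep)))
  }
  imp <- NULL
  if (shap) {
    best <- full$reports$model[which.max(full$reports$auc)]
    imp <- shap_importance(full$models[[best]], full$data, seed = seed)
  }
  structure(list(reports = full$reports,
                 two_feature_reports = if (!is.null(two)) two$reports,
                 importance = imp, data = full$data, models = full$models,
                 seed = seed),
            class = "af_study")
}

#' @export
print.af_study <- function(x, ...) {
  cat("<af_study>\n")
  print(dplyr::select(x$reports, "model", "auc", "accuracy", "sensitivity",
                      "specificity", "precision", "f1"))
  if (!is.null(x$two_feature_reports)) {
    cat("two-feature (P amplitude + duration) models:\n")
    print(dplyr::select(x$two_feature_reports, "model", "auc", "f1"))
  }
  invisible(x)
}

#' Tidy per-model metrics of a study
#'
#' @param x an `af_study`.
#' @param ... unused.
#' @return Tibble with one row per model and metric columns.
#' @export
tidy.af_study <- function(x, ...) {
  full <- dplyr::mutate(x$reports, feature_set = "full")
  if (!is.null(x$two_feature_reports)) {
    two <- dplyr::mutate(x$two_feature_reports, feature_set = "two_feature")
    return(dplyr::bind_rows(full, two))
  }
  full
}

#' One-row study summary
#'
#' @param x an `af_study`.
#' @param ... unused.
#' @return One-row tibble: best model, its AUC and F1, number of features
#'   and of training/test rows.
#' @export
glance.af_study <- function(x, ...) {
  best <- x$reports[which.max(x$reports$auc), ]
  tibble::tibble(
    best_model = best$model, best_auc = best$auc, best_f1 = best$f1,
    n_features = length(setdiff(names(x$data), c("id", "label", "set"))),
    n_train = sum(x$data$set == "train"),
    n_test = sum(x$data$set == "test"))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
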