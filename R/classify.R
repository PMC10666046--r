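#' Train the stage-1 outcome classifier (median-split OS/PFI)
#'
#' Fits the shared feed-forward classifier on patients-by-genes features
#' against the binarized endpoint labels, with stratified k-fold
#' cross-validation. Out-of-fold ROC-AUCs are reported per fold; optional
#' synthetic rows (from [augment_with_gan()]) are appended to every
#' training fold but never scored, so the reported AUC always measures
#' generalization to real patients.
#'
#' @param features genes-by-patients expression matrix (as produced by the
#'   generators) or a patients-by-genes matrix; orientation is resolved via
#'   the label patient ids.
#' @param labels tibble from [binarize_outcome()].
#' @param folds number of CV folds (default 5).
#' @param arch [mlp_arch()] configuration.
#' @param seed integer seed.
#' @param augmented optional augmented table from [augment_with_gan()]
#'   (only its synthetic rows are used).
#' @param log_transform log-transform expression features before fitting
#'   (default TRUE; expression is strictly positive and heavily skewed).
#' @return An `onco_classifier` with a `cv` report; see [predict_proba()],
#'   [tidy()], [glance()].
#' @export
train_outcome_classifier <- function(features, labels, folds = 5L,
                                     arch = mlp_arch(), seed = 1L,
                                     augmented = NULL, log_transform = TRUE) {
  X <- align_features(features, labels$patient_id)
  aug <- prepare_augmented(augmented, colnames(X))
  if (log_transform) {
    X <- safe_log(X)
    if (!is.null(aug)) aug$X <- safe_log(aug$X)
  }
  train_classifier(X, labels$label, folds = folds, arch = arch, seed = seed,
                   augmented = aug, stage = "outcome")
}

#' Train the stage-2 tumor/normal tissue classifier
#'
#' Identical contract to [train_outcome_classifier()], with tissue labels
#' (`tumor` coded 1, `normal` 0).
#'
#' @param expression genes-by-samples matrix.
#' @param labels tibble with `sample_id` and `label` (`"tumor"`/`"normal"`).
#' @inheritParams train_outcome_classifier
#' @export
train_tissue_classifier <- function(expression, labels, folds = 5L,
                                    arch = mlp_arch(), seed = 1L,
                                    log_transform = TRUE) {
  X <- align_features(expression, labels$sample_id)
  if (log_transform) X <- safe_log(X)
  y <- as.integer(labels$label == "tumor")
  if (all(y == 0L) || all(y == 1L)) abort("Both tissue classes must be present.")
  train_classifier(X, y, folds = folds, arch = arch, seed = seed,
                   stage = "tissue")
}

# Accepts genes x samples (generator orientation) or samples x genes and
# returns samples x genes aligned to `ids`.
align_features <- function(features, ids) {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (!is.null(colnames(features)) && all(ids %in% colnames(features))) {
    X <- t(features[, ids, drop = FALSE])
  } else if (!is.null(rownames(features)) && all(ids %in% rownames(features))) {
    X <- features[ids, , drop = FALSE]
  } else {
    abort("Could not align features to label ids (ids missing from dimnames).")
  }
  X
}

prepare_augmented <- function(augmented, feature_names) {
  if (is.null(augmented)) return(NULL)
  if (is.data.frame(augmented)) {
    if (!all(c(".synthetic", "label") %in% names(augmented))) {
      abort("Augmented table must carry `.synthetic` and `label` columns.")
    }
    syn <- augmented[augmented$.synthetic, , drop = FALSE]
    missing <- setdiff(feature_names, names(syn))
    if (length(missing) > 0L) {
      abort(sprintf("Augmented table lacks feature column(s): %s.",
                    paste(head(missing, 5L), collapse = ", ")))
    }
    list(X = as.matrix(syn[, feature_names, drop = FALSE]),
         y = as.integer(as.character(syn$label)))
  } else {
    augmented
  }
}

# Elementwise log for strictly positive expression; values at or below zero
# (possible only in degenerate user input) are floored first.
safe_log <- function(X) {
  eps <- min(X[X > 0], na.rm = TRUE) * 1e-3
  log(pmax(X, eps))
}
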