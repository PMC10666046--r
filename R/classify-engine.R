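# Shared feed-forward classifier engine. Every classifier stage (outcome,
# tissue, drug-protein interaction, IC50 success) uses the same seeded
# single-hidden-layer perceptron with out-of-fold cross-validated AUC.

#' Multi-layer-perceptron architecture configuration
#'
#' @param hidden number of hidden units.
#' @param decay L2 weight decay.
#' @param maxit maximum optimizer iterations.
#' @param max_weights upper bound on network weights (guards against
#'   accidentally huge inputs).
#' @return A list of class `mlp_arch`.
#' @export
mlp_arch <- function(hidden = 12L, decay = 0.01, maxit = 120L,
                     max_weights = 20000L) {
  structure(list(hidden = check_count(hidden, "hidden"),
                 decay = check_scalar(decay, "decay", min = 0),
                 maxit = check_count(maxit, "maxit"),
                 max_weights = check_count(max_weights, "max_weights")),
            class = "mlp_arch")
}

# Fit one standardized MLP. Returns the nnet fit plus the scaling used.
fit_mlp <- function(X, y, arch, seed) {
  mu <- colMeans(X)
  sdev <- apply(X, 2L, sd)
  sdev[sdev == 0 | !is.finite(sdev)] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdev, "/")
  fit <- with_seed(seed, nnet::nnet(
    Xs, y, size = arch$hidden, decay = arch$decay, maxit = arch$maxit,
    entropy = TRUE, MaxNWts = arch$max_weights, trace = FALSE))
  list(fit = fit, mu = mu, sd = sdev)
}

predict_mlp <- function(model, X) {
  Xs <- sweep(sweep(X, 2L, model$mu), 2L, model$sd, "/")
  as.numeric(predict(model$fit, Xs))
}

# Cross-validated training. `augmented` rows (list(X, y)) are appended to
# every training fold but never evaluated, so the CV AUC measures real-row
# generalization only.
train_classifier <- function(X, y, folds = 5L, arch = mlp_arch(), seed = 1L,
                             augmented = NULL, stage = "classifier") {
  folds <- check_count(folds, "folds", min = 2L)
  if (!is.matrix(X)) X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  if (nrow(X) != length(y)) abort("Features and labels are not aligned.")
  if (length(unique(y)) < 2L) abort("Both classes must be present.")
  assign <- stratified_folds(y, folds, seed = derive_seed(seed, "folds"))

  fold_auc <- numeric(folds)
  oof <- numeric(length(y))
  fold_models <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- assign != f
    Xtr <- X[tr, , drop = FALSE]
    ytr <- y[tr]
    if (!is.null(augmented)) {
      Xtr <- rbind(Xtr, augmented$X)
      ytr <- c(ytr, augmented$y)
    }
    m <- fit_mlp(Xtr, ytr, arch, seed = derive_seed(seed, paste0("fold", f)))
    fold_models[[f]] <- m
    p <- predict_mlp(m, X[!tr, , drop = FALSE])
    oof[!tr] <- p
    fold_auc[f] <- roc_auc(y[!tr], p)
  }

  Xfull <- X
  yfull <- y
  if (!is.null(augmented)) {
    Xfull <- rbind(Xfull, augmented$X)
    yfull <- c(yfull, augmented$y)
  }
  final <- fit_mlp(Xfull, yfull, arch, seed = derive_seed(seed, "final"))

  structure(
    list(
      model = final,
      features = colnames(X),
      cv = structure(
        list(fold_aucs = fold_auc,
             mean_auc = mean(fold_auc),
             fold_assignments = assign,
             oof = oof),
        class = "cv_report"),
      fold_models = fold_models,
      arch = arch,
      stage = stage,
      seed = seed
    ),
    class = "onco_classifier"
  )
}

#' Predict class probabilities from a fitted pipeline classifier
#'
#' @param object an `onco_classifier`.
#' @param newdata numeric matrix with the training feature columns.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict_proba <- function(object, newdata) {
  stopifnot(inherits(object, "onco_classifier"))
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$model$mu)) {
    abort(sprintf("Expected %d feature columns, got %d.",
                  length(object$model$mu), ncol(newdata)))
  }
  pmin(pmax(predict_mlp(object$model, newdata), 0), 1)
}

#' @export
print.onco_classifier <- function(x, ...) {
  cat(sprintf("<onco_classifier: %s>\n", x$stage))
  cat(sprintf("  features: %d  hidden: %d  folds: %d\n",
              length(x$features), x$arch$hidden, length(x$cv$fold_aucs)))
  cat(sprintf("  CV AUC: %.3f (folds: %s)\n", x$cv$mean_auc,
              paste(sprintf("%.3f", x$cv$fold_aucs), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.onco_classifier <- function(x, ...) {
  tibble(fold = seq_along(x$cv$fold_aucs), auc = x$cv$fold_aucs)
}

#' @export
glance.onco_classifier <- function(x, ...) {
  tibble(stage = x$stage, mean_auc = x$cv$mean_auc,
         folds = length(x$cv$fold_aucs), n_features = length(x$features),
         hidden = x$arch$hidden, seed = x$seed)
}

# Fold-aggregated permutation importance on held-out folds: permutes each
# feature of the held-out block and records the increase in held-out
# log-loss (binomial deviance) against the fold's model; importance is
# the mean increase over permutations and folds, floored at zero.
# Log-loss stays sensitive when classes separate perfectly, where an
# AUC-based drop would be identically zero. When a trained
# `onco_classifier` is supplied its fold models and assignments are
# reused; otherwise one model per fold is fitted here.
permutation_importance <- function(X, y, folds = 5L, arch = mlp_arch(),
                                   seed = 1L, block = NULL, fitted = NULL,
                                   n_repeats = 3L) {
  if (!is.matrix(X)) X <- as.matrix(X)
  y <- as.integer(y)
  block <- block %||% colnames(X)
  if (!is.null(fitted)) {
    assign <- fitted$cv$fold_assignments
    folds <- length(fitted$cv$fold_aucs)
  } else {
    assign <- stratified_folds(y, folds, seed = derive_seed(seed, "pifolds"))
  }
  drops <- matrix(0, length(block), folds, dimnames = list(block, NULL))
  for (f in seq_len(folds)) {
    tr <- assign != f
    m <- if (!is.null(fitted)) fitted$fold_models[[f]] else
      fit_mlp(X[tr, , drop = FALSE], y[tr], arch,
              seed = derive_seed(seed, paste0("pifold", f)))
    Xte <- X[!tr, , drop = FALSE]
    yte <- y[!tr]
    base <- log_loss(yte, predict_mlp(m, Xte))
    perms <- lapply(seq_len(n_repeats), function(r)
      with_seed(derive_seed(seed, paste0("perm", f, "_", r)),
                sample(nrow(Xte))))
    for (j in block) {
      dj <- 0
      for (perm in perms) {
        Xp <- Xte
        Xp[, j] <- Xp[perm, j]
        dj <- dj + (log_loss(yte, predict_mlp(m, Xp)) - base)
      }
      drops[j, f] <- dj / n_repeats
    }
  }
  imp <- pmax(rowMeans(drops), 0)
  ranking <- tibble(gene = block, importance = imp) %>%
    filter(.data$importance > 0) %>%
    arrange(desc(.data$importance), .data$gene) %>%
    mutate(rank = row_number())
  attr(ranking, "method") <- "permutation"
  ranking
}
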