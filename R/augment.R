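#' Augment a features+label table with synthetic patient rows
#'
#' Emulates tabular generative augmentation of a small cohort: a Gaussian
#' copula is fitted per label class (empirical normal-scores transform of
#' each numeric column, shrunk correlation matrix) and `n_synthetic` rows
#' are sampled from it, preserving each class's marginal distributions and
#' pairwise dependence. Sampled values invert through the empirical
#' quantiles, so every synthetic value lies within the observed range of
#' its column. Synthetic rows are flagged in a `.synthetic` column.
#'
#' @param table data frame of numeric feature columns plus a `label` column
#'   (binary); at least 50 rows.
#' @param n_synthetic number of synthetic rows to append (0 returns the
#'   input unchanged apart from the flag column).
#' @param seed integer seed.
#' @param backend `"copula"` (the implemented sampler). Any other value
#'   warns and falls back to the copula backend with an identical contract.
#' @param shrinkage weight pulling the copula correlation toward the
#'   identity, stabilising estimation on small cohorts.
#' @return The input with `n_synthetic` generated rows appended and a
#'   logical `.synthetic` column.
#' @export
augment_with_gan <- function(table, n_synthetic, seed, backend = "copula",
                             shrinkage = 0.2) {
  n_synthetic <- check_count(n_synthetic, "n_synthetic", min = 0L)
  if (!"label" %in% names(table)) abort("`table` must have a `label` column.")
  if (nrow(table) < 50L) abort("Need at least 50 real rows to fit the sampler.")
  if (!identical(backend, "copula")) {
    warn(sprintf(
      "Backend '%s' is not available; falling back to the Gaussian-copula sampler.",
      backend))
  }
  feat_cols <- setdiff(names(table), c("label", ".synthetic"))
  if (!all(vapply(table[feat_cols], is.numeric, logical(1)))) {
    abort("All feature columns must be numeric.")
  }
  out_real <- table[c(feat_cols, "label")]
  out_real$.synthetic <- FALSE
  if (n_synthetic == 0L) return(as_tibble(out_real))

  labels <- table$label
  classes <- sort(unique(labels))
  props <- as.numeric(table(factor(labels, classes))) / length(labels)
  n_per <- round(n_synthetic * props)
  n_per[length(n_per)] <- n_synthetic - sum(n_per[-length(n_per)])

  syn <- with_seed(seed, {
    pieces <- lapply(seq_along(classes), function(ci) {
      Xc <- as.matrix(table[labels == classes[ci], feat_cols, drop = FALSE])
      s <- copula_sample(Xc, n_per[ci], shrinkage)
      df <- as.data.frame(s)
      names(df) <- feat_cols
      df$label <- classes[ci]
      df
    })
    do.call(rbind, pieces)
  })
  syn$.synthetic <- TRUE
  as_tibble(rbind(out_real, syn))
}

# Rank-based Gaussian copula draw: empirical CDF -> normal scores ->
# shrunk-correlation multivariate normal -> empirical quantile inversion.
copula_sample <- function(X, n, shrinkage) {
  if (n == 0L) return(X[0L, , drop = FALSE])
  m <- nrow(X)
  p <- ncol(X)
  if (m < 3L) abort("Too few rows in a label class to fit the copula.")
  Z <- qnorm((apply(X, 2L, rank, ties.method = "average") - 0.5) / m)
  R <- cor(Z)
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  R <- (1 - shrinkage) * R + shrinkage * diag(p)
  S <- MASS::mvrnorm(n, rep(0, p), R)
  if (n == 1L) S <- matrix(S, 1L)
  U <- pnorm(S)
  out <- vapply(seq_len(p), function(j) {
    as.numeric(quantile(X[, j], probs = U[, j], type = 7))
  }, numeric(n))
  if (n == 1L) out <- matrix(out, 1L)
  colnames(out) <- colnames(X)
  out
}
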