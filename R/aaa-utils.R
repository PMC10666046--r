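# Shared internal helpers: seeded evaluation, AUC, argument checks.

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible child seed from a parent seed and a label, so that
# independent stages never share an RNG stream. Kept below 2^31 - 1.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 2654435761) %% 1e6
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629L + 1)
}

# Rank-statistic ROC AUC (equivalent to the Mann-Whitney U normalisation).
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    abort("AUC undefined: both classes must be present.")
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d (got %s).",
                  name, min, paste(format(x), collapse = ", ")))
  }
  as.integer(x)
}

check_scalar <- function(x, name, min = -Inf, max = Inf) {
  if (length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(min), format(max)))
  }
  as.numeric(x)
}

# Stratified fold assignment; errors when any fold would be single-class.
stratified_folds <- function(labels, folds, seed) {
  labels <- as.integer(labels)
  if (min(table(labels)) < folds) {
    abort(sprintf(
      "Cannot build %d stratified folds: minority class has only %d members.",
      folds, min(table(labels))))
  }
  assign <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      assign[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
  })
  assign
}

# Binomial log-loss (cross-entropy) with probability clipping.
log_loss <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
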