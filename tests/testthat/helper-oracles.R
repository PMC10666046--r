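# Independent brute-force oracles used across tests. Each is written from
# the operation's definition, never from the implementation it checks.

# Q1 lower-quartile negative set by explicit sort/filter.
oracle_quartile_negatives <- function(positives, scores, max_compounds) {
  q1 <- as.numeric(quantile(scores$score, 0.25, type = 7))
  tallies <- table(scores$compound_id)
  ord <- order(-as.numeric(tallies), names(tallies))
  keep <- names(tallies)[ord][seq_len(min(max_compounds, length(tallies)))]
  pos_key <- paste(positives$protein_id, positives$compound_id)
  out <- scores[scores$score <= q1 & scores$compound_id %in% keep, ]
  out[!paste(out$protein_id, out$compound_id) %in% pos_key,
      c("protein_id", "compound_id")]
}

# Count-and-sort selectivity ranking by direct enumeration.
oracle_selectivity <- function(mat, threshold, required, top_n) {
  pass <- rownames(mat)[apply(mat[, required, drop = FALSE] > threshold,
                              1, all)]
  if (length(pass) == 0L) return(character(0))
  off <- setdiff(colnames(mat), required)
  n_hit <- sapply(pass, function(m) sum(mat[m, ] > threshold))
  mo <- sapply(pass, function(m)
    if (length(off)) mean(mat[m, off]) else 0)
  ord <- order(n_hit, mo, pass)
  head(pass[ord], top_n)
}

# Token-count brute-force sum embedding.
oracle_sum_embedding <- function(tokens, vectors) {
  out <- rep(0, ncol(vectors))
  for (t in tokens) {
    if (t %in% rownames(vectors)) out <- out + vectors[t, ]
  }
  out
}

# Document-level whole-token co-occurrence by direct regex search.
oracle_cooccurrence <- function(texts, gene, keyword) {
  hit <- function(term) {
    grepl(paste0("(?<![[:alnum:]_])",
                 gsub("([][{}()+*^$|\\\\?.-])", "\\\\\\1", term),
                 "(?![[:alnum:]_])"),
          texts, perl = TRUE, ignore.case = TRUE)
  }
  sum(hit(gene) & hit(keyword))
}

# Small labeled feature set for fast classifier-contract tests.
tiny_classification_data <- function(n = 80L, p = 6L, signal = 2, seed = 1L) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- as.integer(runif(n) < plogis(signal * X[, 1]))
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  list(X = X, y = y)
}

fast_arch <- function() mlp_arch(hidden = 4L, maxit = 60L)
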