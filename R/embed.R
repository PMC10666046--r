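# Token embeddings: amino-acid triplet sentences for proteins, circular
# substructure sentences for compounds, and a deterministic skip-gram-style
# embedding trained by positive-PMI co-occurrence factorization. A protein
# or compound vector is the sum of its token vectors.

#' Build the k-mer sentence corpus of a set of protein sequences
#'
#' Each sequence yields `k` shifted non-overlapping readings (offsets
#' `0..k-1`); each reading is a sentence of consecutive k-mers, dropping
#' residues at the tail that do not complete a k-mer. For k = 3 this is the
#' classic amino-acid-triplet vocabulary of at most 8,000 tokens.
#'
#' @param proteins tibble with a `sequence` column, or a character vector.
#' @param k k-mer size (default 3).
#' @param mode `"shifted"` (k non-overlapping readings, the default) or
#'   `"sliding"` (one sentence of all overlapping k-mers).
#' @return List of character vectors (sentences). Sequences shorter than
#'   `k` are skipped with a warning.
#' @export
protein_corpus <- function(proteins, k = 3L, mode = c("shifted", "sliding")) {
  mode <- match.arg(mode)
  k <- check_count(k, "k", min = 1L)
  seqs <- if (is.data.frame(proteins)) proteins$sequence else proteins
  short <- nchar(seqs) < k
  if (any(short)) {
    warn(sprintf("Skipping %d sequence(s) shorter than k = %d.",
                 sum(short), k))
    seqs <- seqs[!short]
  }
  sentences <- list()
  for (s in seqs) {
    n <- nchar(s)
    if (mode == "sliding") {
      starts <- seq_len(n - k + 1L)
      sentences[[length(sentences) + 1L]] <-
        substring(s, starts, starts + k - 1L)
    } else {
      for (off in 0:(k - 1L)) {
        if (1L + off > n - k + 1L) next
        starts <- seq(1L + off, n - k + 1L, by = k)
        sentences[[length(sentences) + 1L]] <-
          substring(s, starts, starts + k - 1L)
      }
    }
  }
  sentences
}

#' Build substructure sentences for a compound library
#'
#' @param compounds tibble with `smiles` (and optionally `id`) columns, or
#'   a character vector of SMILES.
#' @param radius circular-environment radius passed to
#'   [compound_sentence()].
#' @return List of character vectors, one sentence per compound.
#' @export
compound_corpus <- function(compounds, radius = 1L) {
  smiles <- if (is.data.frame(compounds)) compounds$smiles else compounds
  ids <- if (is.data.frame(compounds) && "id" %in% names(compounds))
    compounds$id else NULL
  graphs <- parse_smiles_graphs(smiles, ids)
  lapply(graphs, function(g) {
    inv <- atom_environment_tokens(g, radius)
    n <- length(g$elements)
    unlist(lapply(seq_len(n), function(a)
      sprintf("r%d:%s", seq(0L, radius), vapply(seq_len(radius + 1L),
        function(r) inv[[r]][a], character(1)))))
  })
}

#' Train a token embedding table from a sentence corpus
#'
#' Deterministic skip-gram-style embedding: symmetric windowed
#' co-occurrence counts are transformed to positive pointwise mutual
#' information and factorized by a seeded randomized SVD; each token's
#' vector is its left singular row scaled by the square-rooted singular
#' values. Every token occurring in the corpus receives a vector.
#'
#' @param corpus list of character vectors (sentences).
#' @param d embedding dimension (default 100, >= 2).
#' @param window symmetric co-occurrence window (default 5).
#' @param epochs power-iteration count of the randomized factorization.
#' @param seed integer seed.
#' @param kind token kind tag, `"aa_3mer"` or `"substructure_id"`.
#' @param k k-mer size recorded for protein tables (metadata only).
#' @param radius environment radius recorded for compound tables.
#' @return A `kmer_embedding_table`: list with `vectors` (tokens x d
#'   matrix), `kind`, `d`, `window`, `seed`, and `k`/`radius`.
#' @export
train_token_embedding <- function(corpus, d = 100L, window = 5L, epochs = 2L,
                                  seed = 1L, kind = "aa_3mer", k = 3L,
                                  radius = 1L) {
  d <- check_count(d, "d", min = 2L)
  window <- check_count(window, "window", min = 1L)
  epochs <- check_count(epochs, "epochs", min = 0L)
  corpus <- corpus[lengths(corpus) > 0L]
  if (length(corpus) == 0L) abort("Corpus is empty.")
  vocab <- sort(unique(unlist(corpus, use.names = FALSE)))
  V <- length(vocab)

  ii <- integer(0); jj <- integer(0)
  for (sent in corpus) {
    ix <- match(sent, vocab)
    n <- length(ix)
    for (off in seq_len(min(window, n - 1L))) {
      a <- ix[seq_len(n - off)]
      bb <- ix[seq(off + 1L, n)]
      ii <- c(ii, a, bb)
      jj <- c(jj, bb, a)
    }
  }
  C <- if (length(ii) == 0L) {
    Matrix::sparseMatrix(i = 1L, j = 1L, x = 0, dims = c(V, V))
  } else {
    Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(V, V))
  }
  # positive PMI on the non-zero entries
  total <- sum(C)
  if (total > 0) {
    rs <- Matrix::rowSums(C)
    cs <- Matrix::colSums(C)
    T_ <- methods::as(C, "TsparseMatrix")
    pmi <- log(pmax(T_@x, 1e-12) * total /
                 (rs[T_@i + 1L] * cs[T_@j + 1L]))
    T_@x <- pmax(pmi, 0)
    A <- methods::as(T_, "CsparseMatrix")
  } else {
    A <- C
  }

  vectors <- with_seed(derive_seed(seed, "rsvd"), {
    deff <- min(d, V)
    p <- min(V, deff + 10L)
    Omega <- matrix(rnorm(V * p), V, p)
    Y <- as.matrix(A %*% Omega)
    for (it in seq_len(epochs)) {
      Y <- as.matrix(A %*% as.matrix(Matrix::crossprod(A, qr.Q(qr(Y)))))
    }
    Q <- qr.Q(qr(Y))
    B <- as.matrix(Matrix::crossprod(Q, A))
    sv <- svd(B)
    W <- Q %*% sv$u[, seq_len(deff), drop = FALSE] %*%
      diag(sqrt(sv$d[seq_len(deff)]), deff)
    if (deff < d) W <- cbind(W, matrix(0, V, d - deff))
    rownames(W) <- vocab
    W
  })
  structure(
    list(vectors = vectors, kind = kind, d = d, window = window,
         seed = seed, k = if (kind == "aa_3mer") k else NA_integer_,
         radius = if (kind == "substructure_id") radius else NA_integer_),
    class = "kmer_embedding_table"
  )
}

#' @export
print.kmer_embedding_table <- function(x, ...) {
  cat(sprintf("<kmer_embedding_table: %s, %d tokens x %d dims>\n",
              x$kind, nrow(x$vectors), x$d))
  invisible(x)
}

sum_token_vectors <- function(tokens, table, oov_rule) {
  counts <- table(tokens)
  tok <- names(counts)
  known <- tok %in% rownames(table$vectors)
  n_oov <- sum(counts[!known])
  if (n_oov > 0L && oov_rule == "error") {
    abort(sprintf("%d out-of-vocabulary token(s): %s.", n_oov,
                  paste(head(tok[!known], 3L), collapse = ", ")))
  }
  v <- if (any(known)) {
    as.numeric(crossprod(table$vectors[tok[known], , drop = FALSE],
                         as.numeric(counts[known])))
  } else {
    rep(0, table$d)
  }
  attr(v, "n_oov") <- as.integer(n_oov)
  v
}

#' Embed a protein sequence as the sum of its k-mer vectors
#'
#' Tokens come from the shifted non-overlapping readings of
#' [protein_corpus()]; the embedding is the sum of the corresponding
#' vectors, so it equals the token-count-weighted sum of table rows.
#' Out-of-vocabulary tokens contribute zero and are counted in the
#' `n_oov` attribute (default rule), or raise an error.
#'
#' @param sequence a single amino-acid sequence (length >= k).
#' @param table a `kmer_embedding_table` of kind `"aa_3mer"`.
#' @param oov_rule `"zero"` or `"error"`.
#' @return Numeric vector of length `table$d` with an `n_oov` attribute.
#' @export
embed_protein <- function(sequence, table, oov_rule = c("zero", "error")) {
  oov_rule <- match.arg(oov_rule)
  stopifnot(inherits(table, "kmer_embedding_table"))
  if (table$kind != "aa_3mer") abort("Table kind must be 'aa_3mer'.")
  if (nchar(sequence) < table$k) {
    abort(sprintf("Sequence shorter than k = %d.", table$k))
  }
  tokens <- unlist(protein_corpus(sequence, k = table$k), use.names = FALSE)
  sum_token_vectors(tokens, table, oov_rule)
}

#' Embed a compound as the sum of its substructure-token vectors
#'
#' @param smiles a single SMILES string (parse errors propagate).
#' @param table a `kmer_embedding_table` of kind `"substructure_id"`.
#' @inheritParams embed_protein
#' @export
embed_compound <- function(smiles, table, oov_rule = c("zero", "error")) {
  oov_rule <- match.arg(oov_rule)
  stopifnot(inherits(table, "kmer_embedding_table"))
  if (table$kind != "substructure_id") {
    abort("Table kind must be 'substructure_id'.")
  }
  tokens <- compound_sentence(smiles, radius = table$radius)
  sum_token_vectors(tokens, table, oov_rule)
}

# Vectorized embedding helpers returning items x d matrices.
embed_proteins_matrix <- function(proteins, table, oov_rule = "zero") {
  m <- t(vapply(proteins$sequence, function(s)
    as.numeric(embed_protein(s, table, oov_rule)), numeric(table$d)))
  rownames(m) <- proteins$id
  m
}

embed_compounds_matrix <- function(compounds, table, oov_rule = "zero") {
  sentences <- compound_corpus(compounds, radius = table$radius)
  m <- t(vapply(sentences, function(tok)
    as.numeric(sum_token_vectors(tok, table, oov_rule)), numeric(table$d)))
  rownames(m) <- compounds$id
  m
}

#' Write / read an embedding table as annotated TSV
#'
#' The first line is a `#`-prefixed header recording kind, dimension,
#' window, k/radius and training seed; the table round-trips losslessly.
#'
#' @param table a `kmer_embedding_table`.
#' @param path file path.
#' @export
write_embedding_table <- function(table, path) {
  hdr <- sprintf("# kind=%s d=%d window=%d k=%s radius=%s seed=%d",
                 table$kind, table$d, table$window,
                 table$k, table$radius, table$seed)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(
    data.frame(token = rownames(table$vectors), table$vectors,
               check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_embedding_table
#' @export
read_embedding_table <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- strsplit(sub("^# ", "", hdr), " ")[[1L]]
  kv <- strsplit(meta, "=")
  vals <- setNames(vapply(kv, `[`, character(1), 2L),
                   vapply(kv, `[`, character(1), 1L))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          check.names = FALSE, comment.char = "")
  vectors <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vectors) <- df$token
  colnames(vectors) <- NULL
  structure(
    list(vectors = vectors, kind = vals[["kind"]],
         d = as.integer(vals[["d"]]), window = as.integer(vals[["window"]]),
         seed = as.integer(vals[["seed"]]),
         k = suppressWarnings(as.integer(vals[["k"]])),
         radius = suppressWarnings(as.integer(vals[["radius"]]))),
    class = "kmer_embedding_table"
  )
}
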