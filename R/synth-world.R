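#' Generate a synthetic drug-protein interaction world
#'
#' Labels every (protein, compound) pair by a hidden rule -- the dot product
#' of the records' latent vectors exceeding the `1 - pos_fraction` quantile
#' -- and draws an interaction-score table in which positive pairs receive
#' high scores (uniform on \[0.85, 1\]) and all other pairs bulk scores
#' (Beta(2, 10)). At the defaults the positive score range sits strictly
#' above the upper whisker (Q3 + 1.5 IQR) of the pooled score distribution,
#' reproducing the outlier structure that justifies lower-quartile negative
#' sampling.
#'
#' @param proteins tibble from [generate_proteins()] (latents attached).
#' @param compounds tibble from [generate_compounds()].
#' @param pos_fraction fraction of pairs labelled positive, in (0, 0.5).
#' @param seed integer seed.
#' @return A `syn_interaction_world` list: `proteins`, `compounds`,
#'   `score_table` (tibble: compound_id, protein_id, score),
#'   `positive_pairs` (tibble: protein_id, compound_id), `planted_rule`
#'   (description string). Hidden latents are kept as attributes.
#' @export
generate_interaction_world <- function(proteins, compounds,
                                       pos_fraction = 0.1, seed) {
  pos_fraction <- check_scalar(pos_fraction, "pos_fraction", 1e-9, 0.5 - 1e-9)
  zp <- attr(proteins, "latents")
  zc <- attr(compounds, "latents")
  if (is.null(zp) || is.null(zc)) {
    abort("`proteins` and `compounds` must come from the synthetic generators (latents attribute required).")
  }
  with_seed(seed, {
    dots <- zp %*% t(zc)
    cutoff <- quantile(dots, 1 - pos_fraction, type = 7)
    pos_idx <- which(dots > cutoff, arr.ind = TRUE)
    pairs <- expand.grid(p = seq_len(nrow(zp)), c = seq_len(ncol(t(zc))),
                         KEEP.OUT.ATTRS = FALSE)
    is_pos <- as.vector(dots > cutoff)
    score <- rbeta(nrow(pairs), 2, 10)
    score[is_pos] <- runif(sum(is_pos), 0.85, 1)
    score_table <- tibble(
      compound_id = compounds$id[pairs$c],
      protein_id = proteins$id[pairs$p],
      score = score
    )
    positive_pairs <- tibble(
      protein_id = proteins$id[pos_idx[, 1L]],
      compound_id = compounds$id[pos_idx[, 2L]]
    )
    structure(
      list(
        proteins = proteins,
        compounds = compounds,
        score_table = score_table,
        positive_pairs = positive_pairs,
        planted_rule = sprintf(
          "positive iff <z_protein, z_compound> > %.4f (the %.0f%% quantile of all pair dot products)",
          cutoff, 100 * (1 - pos_fraction)),
        cutoff = as.numeric(cutoff),
        seed = seed
      ),
      class = "syn_interaction_world"
    )
  })
}

# Direct evaluation of the hidden interaction rule, used by oracle tests.
world_rule_labels <- function(world) {
  zp <- attr(world$proteins, "latents")
  zc <- attr(world$compounds, "latents")
  dots <- zp %*% t(zc)
  key <- paste(world$positive_pairs$protein_id, world$positive_pairs$compound_id)
  all_pairs <- expand.grid(p = rownames(zp), c = rownames(zc),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tibble(
    protein_id = all_pairs$p,
    compound_id = all_pairs$c,
    dot = as.vector(dots),
    positive = paste(all_pairs$p, all_pairs$c) %in% key
  )
}

#' Generate a synthetic cell-line sensitivity panel
#'
#' Cell-line expression profiles are drawn log-normal over a gene set; the
#' binary IC50-success label of a (line, compound) record follows a logistic
#' model on the interaction between the line's planted driver-gene score and
#' the compound's hidden latent, so sensitivity is predictable only from the
#' expression block together with the compound structure.
#'
#' @param genes a `syn_tissue_panel`, or a character vector of gene ids.
#' @param compounds tibble from [generate_compounds()].
#' @param n_lines number of cell lines (>= 2).
#' @param seed integer seed.
#' @param n_driver_genes number of planted sensitivity drivers (0 = null
#'   panel: labels independent of expression).
#' @param gain logistic slope of the driver x latent interaction.
#' @param coverage fraction of the line-by-compound grid that receives a
#'   sensitivity record (partial crossing, as in real panels).
#' @return A `syn_sensitivity_panel` list: `lines` (genes x lines matrix),
#'   `sensitivity` (tibble: line_id, compound_id, success),
#'   `planted_gene_set`, `compounds`.
#' @export
generate_sensitivity_panel <- function(genes, compounds, n_lines = 106L, seed,
                                       n_driver_genes = 20L, gain = 12,
                                       coverage = 0.88) {
  if (inherits(genes, "syn_tissue_panel")) genes <- rownames(genes$expression)
  stopifnot(is.character(genes), length(genes) >= 1L)
  n_lines <- check_count(n_lines, "n_lines", min = 2L)
  n_driver_genes <- check_count(n_driver_genes, "n_driver_genes", min = 0L)
  if (n_driver_genes > length(genes)) {
    abort("`n_driver_genes` must not exceed the number of genes.")
  }
  zc <- attr(compounds, "latents")
  if (is.null(zc)) abort("`compounds` must carry generator latents.")
  with_seed(seed, {
    line_ids <- sprintf("LINE%03d", seq_len(n_lines))
    meanlog <- rnorm(length(genes), 3, 0.7)
    logx <- matrix(rnorm(length(genes) * n_lines), length(genes), n_lines) *
      0.8 + meanlog
    expr <- exp(logx)
    dimnames(expr) <- list(genes, line_ids)

    drivers <- if (n_driver_genes > 0L) sort(sample(genes, n_driver_genes))
               else character(0)
    s_line <- rep(0, n_lines)
    if (n_driver_genes > 0L) {
      zs <- scale(t(logx[match(drivers, genes), , drop = FALSE]))
      s_line <- rowSums(zs) / sqrt(n_driver_genes)
    }
    u_c <- zc[, 1L]

    grid <- expand.grid(l = seq_len(n_lines), c = seq_len(nrow(compounds)),
                        KEEP.OUT.ATTRS = FALSE)
    keep <- runif(nrow(grid)) < coverage
    grid <- grid[keep, , drop = FALSE]
    eta <- gain * s_line[grid$l] * u_c[grid$c]
    success <- as.integer(runif(nrow(grid)) < plogis(eta))
    structure(
      list(
        lines = expr,
        sensitivity = tibble(
          line_id = line_ids[grid$l],
          compound_id = compounds$id[grid$c],
          success = success
        ),
        planted_gene_set = drivers,
        compounds = compounds,
        gain = gain,
        seed = seed
      ),
      class = "syn_sensitivity_panel"
    )
  })
}

# Filler vocabulary for the corpus generator: plain lowercase words that can
# never collide with gene symbols, inhibitor names or query keywords.
FILLER_WORDS <- c(
  "the", "observed", "cells", "were", "treated", "with", "vehicle",
  "control", "and", "assayed", "after", "incubation", "response", "was",
  "measured", "using", "standard", "protocols", "results", "suggest",
  "further", "work", "is", "needed", "to", "confirm", "these", "findings",
  "in", "model", "systems", "samples", "showed", "variable", "expression")

#' Generate a synthetic abstract corpus with planted gene/inhibitor mentions
#'
#' Documents are built from sentence templates. Three sentence kinds exist:
#' a gene-inhibitor sentence (plants an extractable pair), a gene-keyword
#' sentence (plants a co-occurrence), and filler. All planted tuples and
#' per-document gene/keyword placements are returned as ground truth.
#'
#' @param genes character vector of gene symbols.
#' @param inhibitors character vector of inhibitor names (typically -inib /
#'   -tinib style names or development codes so pattern NER can find them).
#' @param keywords character vector of query keywords.
#' @param n_docs number of documents (>= 1).
#' @param seed integer seed.
#' @return A `syn_corpus` list: `corpus` (tibble: id, text), `tuples`
#'   (tibble: doc_id, gene, inhibitor), `gene_keyword` (tibble: doc_id,
#'   gene, keyword).
#' @export
generate_corpus <- function(genes, inhibitors, keywords, n_docs, seed) {
  n_docs <- check_count(n_docs, "n_docs", min = 1L)
  stopifnot(length(genes) >= 1L, length(inhibitors) >= 1L,
            length(keywords) >= 1L)
  with_seed(seed, {
    docs <- character(n_docs)
    tuples <- list()
    gk <- list()
    for (d in seq_len(n_docs)) {
      doc_id <- sprintf("DOC%05d", d)
      n_sent <- sample(2:5, 1L)
      sents <- character(n_sent)
      for (s in seq_len(n_sent)) {
        kind <- sample(c("pair", "keyword", "filler"), 1L,
                       prob = c(0.3, 0.35, 0.35))
        filler <- function(k) paste(sample(FILLER_WORDS, k, TRUE), collapse = " ")
        if (kind == "pair") {
          g <- sample(genes, 1L)
          i <- sample(inhibitors, 1L)
          sents[s] <- sprintf("%s signaling was suppressed by %s %s.",
                              g, i, filler(4L))
          tuples[[length(tuples) + 1L]] <-
            tibble(doc_id = doc_id, gene = g, inhibitor = i)
        } else if (kind == "keyword") {
          g <- sample(genes, 1L)
          w <- sample(keywords, 1L)
          sents[s] <- sprintf("%s has been studied in %s models %s.",
                              g, w, filler(3L))
          gk[[length(gk) + 1L]] <-
            tibble(doc_id = doc_id, gene = g, keyword = w)
        } else {
          sents[s] <- paste0(filler(sample(6:10, 1L)), ".")
        }
      }
      docs[d] <- paste(sents, collapse = " ")
    }
    structure(
      list(
        corpus = tibble(id = sprintf("DOC%05d", seq_len(n_docs)), text = docs),
        tuples = if (length(tuples)) distinct(bind_rows(tuples)) else
          tibble(doc_id = character(), gene = character(),
                 inhibitor = character()),
        gene_keyword = if (length(gk)) distinct(bind_rows(gk)) else
          tibble(doc_id = character(), gene = character(),
                 keyword = character()),
        seed = seed
      ),
      class = "syn_corpus"
    )
  })
}
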