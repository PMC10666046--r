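# Stage 4: drug-protein interaction dataset assembly, training, screening.

#' Summarize positive-pair scores against the full score distribution
#'
#' Computes five-number summaries (type-7 quartiles) for the scores of the
#' known positive pairs and for all scores, and flags whether the positive
#' range overlaps the bulk: overlap is declared iff the minimum positive
#' score does not exceed the upper whisker (Q3 + 1.5 IQR) of all scores.
#' Non-overlap is the structural justification for treating lower-quartile
#' scores as negatives.
#'
#' @param scores tibble `(compound_id, protein_id, score)` with scores in
#'   \[0, 1\] and no duplicate pairs.
#' @param positives tibble `(protein_id, compound_id)` of known positives.
#' @return A `dpi_overlap_summary`: list with `summary` (tibble, one row
#'   per group), `overlap` flag, `upper_whisker`, `min_positive`.
#' @export
positive_overlap_summary <- function(scores, positives) {
  key_all <- paste(scores$protein_id, scores$compound_id)
  key_pos <- paste(positives$protein_id, positives$compound_id)
  missing <- setdiff(key_pos, key_all)
  if (length(missing) > 0L) {
    warn(sprintf("%d positive pair(s) absent from the score table; excluded: %s",
                 length(missing), paste(head(missing, 3L), collapse = "; ")))
    key_pos <- setdiff(key_pos, missing)
  }
  pos_scores <- scores$score[key_all %in% key_pos]
  if (length(pos_scores) < 4L || nrow(scores) < 4L) {
    abort("Need at least 4 scores in each group.")
  }
  five <- function(x) {
    q <- quantile(x, c(0, 0.25, 0.5, 0.75, 1), type = 7)
    tibble(min = q[[1L]], q1 = q[[2L]], median = q[[3L]], q3 = q[[4L]],
           max = q[[5L]])
  }
  s_all <- five(scores$score)
  s_pos <- five(pos_scores)
  whisker <- s_all$q3 + 1.5 * (s_all$q3 - s_all$q1)
  structure(
    list(
      summary = bind_rows(
        mutate(s_pos, group = "positive", n = length(pos_scores)),
        mutate(s_all, group = "all", n = nrow(scores))
      ) %>% select("group", "n", "min", "q1", "median", "q3", "max"),
      overlap = s_pos$min <= whisker,
      upper_whisker = whisker,
      min_positive = s_pos$min
    ),
    class = "dpi_overlap_summary"
  )
}

#' @export
print.dpi_overlap_summary <- function(x, ...) {
  cat("<dpi_overlap_summary>\n")
  print(x$summary)
  cat(sprintf("  upper whisker (all): %.4f  min positive: %.4f  overlap: %s\n",
              x$upper_whisker, x$min_positive, x$overlap))
  invisible(x)
}

#' Assemble the labeled drug-protein interaction dataset
#'
#' Positives are the supplied interaction pairs. Negatives are pairs whose
#' interaction score lies at or below the first quartile (type 7) of the
#' full score distribution, restricted to the `max_compounds` compounds
#' with the most scored protein interactions (ties broken lexicographically
#' by compound id); any pair also present in the positives is excluded from
#' the negatives. When embedding matrices are supplied, concatenated
#' (protein, compound) feature rows are attached.
#'
#' @param positives tibble `(protein_id, compound_id)`.
#' @param scores tibble `(compound_id, protein_id, score)`.
#' @param max_compounds cap on distinct negative-pool compounds
#'   (default 50000).
#' @param protein_vectors,compound_vectors optional id-rowed embedding
#'   matrices from the embeddings module.
#' @return Tibble `(protein_id, compound_id, label, provenance)` with
#'   attribute `features` (row-aligned matrix) when vectors were given.
#' @export
assemble_dpi_dataset <- function(positives, scores, max_compounds = 50000L,
                                 protein_vectors = NULL,
                                 compound_vectors = NULL) {
  if (nrow(positives) == 0L) abort("`positives` must be non-empty.")
  if (nrow(scores) == 0L) abort("`scores` must be non-empty.")
  max_compounds <- check_count(max_compounds, "max_compounds")
  q1 <- quantile(scores$score, 0.25, type = 7)

  n_int <- scores %>% count(.data$compound_id, name = "n_scored")
  keep_compounds <- n_int %>%
    arrange(desc(.data$n_scored), .data$compound_id) %>%
    slice_head(n = max_compounds) %>%
    pull(.data$compound_id)

  pos_key <- paste(positives$protein_id, positives$compound_id)
  negatives <- scores %>%
    filter(.data$score <= q1,
           .data$compound_id %in% keep_compounds,
           !paste(.data$protein_id, .data$compound_id) %in% pos_key)
  if (nrow(negatives) == 0L) {
    abort("Lower-quartile rule produced zero negatives.")
  }
  dataset <- bind_rows(
    tibble(protein_id = positives$protein_id,
           compound_id = positives$compound_id,
           label = 1L, provenance = "positive_list"),
    tibble(protein_id = negatives$protein_id,
           compound_id = negatives$compound_id,
           label = 0L, provenance = "quartile_negative")
  )
  attr(dataset, "q1") <- as.numeric(q1)
  if (!is.null(protein_vectors) && !is.null(compound_vectors)) {
    miss_p <- setdiff(unique(dataset$protein_id), rownames(protein_vectors))
    miss_c <- setdiff(unique(dataset$compound_id), rownames(compound_vectors))
    if (length(miss_p) || length(miss_c)) {
      abort("Embeddings missing for some dataset proteins/compounds.")
    }
    feat <- cbind(protein_vectors[dataset$protein_id, , drop = FALSE],
                  compound_vectors[dataset$compound_id, , drop = FALSE])
    rownames(feat) <- NULL
    colnames(feat) <- c(sprintf("p%03d", seq_len(ncol(protein_vectors))),
                        sprintf("c%03d", seq_len(ncol(compound_vectors))))
    attr(dataset, "features") <- feat
  }
  dataset
}

#' Train the drug-protein interaction classifier
#'
#' Fits the shared MLP on concatenated (protein, compound) embedding rows
#' (2d-dimensional; 200 at the default d = 100) with stratified CV.
#'
#' @param dataset output of [assemble_dpi_dataset()] with features
#'   attached.
#' @inheritParams train_outcome_classifier
#' @export
train_dpi_model <- function(dataset, folds = 5L, arch = mlp_arch(),
                            seed = 1L) {
  feat <- attr(dataset, "features")
  if (is.null(feat) || nrow(feat) != nrow(dataset)) {
    abort("Dataset has no attached (row-aligned) feature matrix.")
  }
  model <- train_classifier(feat, dataset$label, folds = folds, arch = arch,
                            seed = seed, stage = "dpi")
  model$feature_dim <- ncol(feat)
  model
}

#' Screen a compound library against target proteins
#'
#' Embeds every protein and compound, scores all pairs with the trained
#' interaction model, and returns hits with probability strictly above the
#' threshold, sorted by probability (descending), ties by protein then
#' compound id. Compounds that fail to embed are skipped, counted, and
#' reported in the `n_skipped` attribute.
#'
#' @param model a trained `onco_classifier` from [train_dpi_model()].
#' @param proteins tibble `(id, sequence)`.
#' @param library tibble `(id, smiles)`.
#' @param protein_table,compound_table embedding tables.
#' @param threshold hit threshold in \[0, 1\].
#' @return Tibble `(protein_id, compound_id, probability)`.
#' @export
screen_library <- function(model, proteins, library, protein_table,
                           compound_table, threshold = 0.99) {
  threshold <- check_scalar(threshold, "threshold", 0, 1)
  EP <- embed_proteins_matrix(proteins, protein_table)
  ok <- rep(TRUE, nrow(library))
  EC <- matrix(0, nrow(library), compound_table$d,
               dimnames = list(library$id, NULL))
  for (i in seq_len(nrow(library))) {
    v <- tryCatch(embed_compound(library$smiles[i], compound_table),
                  error = function(e) NULL)
    if (is.null(v)) ok[i] <- FALSE else EC[i, ] <- v
  }
  if (any(!ok)) {
    warn(sprintf("Skipped %d unembeddable compound(s).", sum(!ok)))
  }
  EC <- EC[ok, , drop = FALSE]
  grid <- expand.grid(p = seq_len(nrow(EP)), c = seq_len(nrow(EC)),
                      KEEP.OUT.ATTRS = FALSE)
  X <- cbind(EP[grid$p, , drop = FALSE], EC[grid$c, , drop = FALSE])
  # floor at a tiny positive value so `threshold = 0` means "no filter"
  prob <- pmax(predict_proba(model, X), 1e-12)
  hits <- tibble(
    protein_id = rownames(EP)[grid$p],
    compound_id = rownames(EC)[grid$c],
    probability = prob
  ) %>%
    filter(.data$probability > threshold) %>%
    arrange(desc(.data$probability), .data$protein_id, .data$compound_id)
  attr(hits, "n_skipped") <- sum(!ok)
  attr(hits, "n_pairs_scored") <- nrow(grid)
  hits
}

#' Tally screening hits per target gene/protein
#'
#' @param hits tibble from [screen_library()].
#' @return Tibble `(gene, n_inhibitors)` sorted by decreasing count.
#' @export
tally_hits_per_gene <- function(hits) {
  if (nrow(hits) == 0L) {
    return(tibble(gene = character(), n_inhibitors = integer()))
  }
  hits %>%
    count(gene = .data$protein_id, name = "n_inhibitors") %>%
    arrange(desc(.data$n_inhibitors), .data$gene)
}
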