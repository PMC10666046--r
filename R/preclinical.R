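# Stage 5: cell-line IC50-success emulation and selectivity screening.

#' Assemble the cell-line sensitivity training set
#'
#' One row per sensitivity record: the cell line's expression profile
#' concatenated with the compound's embedding vector, labeled by the
#' binary IC50-success flag. Records whose line profile or compound vector
#' is missing are excluded with a warning.
#'
#' @param lines genes-by-lines expression matrix.
#' @param sensitivity tibble `(line_id, compound_id, success)`.
#' @param compound_vectors id-rowed compound embedding matrix.
#' @return Tibble `(line_id, compound_id, success)` with attributes
#'   `features` (row-aligned matrix: expression block then compound block)
#'   and `gene_block` (the expression column names).
#' @export
assemble_cell_dataset <- function(lines, sensitivity, compound_vectors) {
  ok_line <- sensitivity$line_id %in% colnames(lines)
  ok_cmp <- sensitivity$compound_id %in% rownames(compound_vectors)
  bad <- !(ok_line & ok_cmp)
  if (any(bad)) {
    warn(sprintf("Excluding %d record(s) with missing line profile or compound vector.",
                 sum(bad)))
    sensitivity <- sensitivity[!bad, , drop = FALSE]
  }
  if (nrow(sensitivity) == 0L) {
    out <- sensitivity
    attr(out, "features") <- matrix(0, 0L, nrow(lines) + ncol(compound_vectors))
    attr(out, "gene_block") <- rownames(lines)
    return(out)
  }
  expr_block <- t(safe_log(lines))[sensitivity$line_id, , drop = FALSE]
  cmp_block <- compound_vectors[sensitivity$compound_id, , drop = FALSE]
  feat <- cbind(expr_block, cmp_block)
  rownames(feat) <- NULL
  colnames(feat) <- c(rownames(lines),
                      sprintf("c%03d", seq_len(ncol(compound_vectors))))
  attr(sensitivity, "features") <- feat
  attr(sensitivity, "gene_block") <- rownames(lines)
  sensitivity
}

#' Train the IC50-success classifier and rank driver genes
#'
#' Fits the shared MLP on (expression, compound-vector) rows and computes
#' fold-aggregated permutation importance restricted to the expression
#' block, producing the driver-gene ranking.
#'
#' @param dataset output of [assemble_cell_dataset()].
#' @inheritParams train_outcome_classifier
#' @return An `onco_classifier` with an extra `gene_ranking` element.
#' @export
train_ic50_model <- function(dataset, folds = 5L, arch = mlp_arch(),
                             seed = 1L) {
  feat <- attr(dataset, "features")
  genes <- attr(dataset, "gene_block")
  if (is.null(feat)) abort("Dataset has no attached feature matrix.")
  y <- dataset$success
  if (length(unique(y)) < 2L) abort("Both outcome classes must be present.")
  model <- train_classifier(feat, y, folds = folds, arch = arch, seed = seed,
                            stage = "ic50")
  model$gene_ranking <- permutation_importance(
    feat, y, arch = arch, seed = derive_seed(seed, "ic50imp"),
    block = genes, fitted = model)
  model
}

#' Predict the molecules-by-lines IC50-success probability matrix
#'
#' @param model trained `onco_classifier` from [train_ic50_model()].
#' @param candidates tibble `(id, smiles)` of candidate molecules.
#' @param lines genes-by-lines expression matrix (same gene block as
#'   training).
#' @param compound_table substructure embedding table.
#' @return Numeric matrix (molecules x lines) of probabilities; candidates
#'   that fail to embed are dropped with a warning.
#' @export
predict_matrix <- function(model, candidates, lines, compound_table) {
  EC <- matrix(NA_real_, nrow(candidates), compound_table$d,
               dimnames = list(candidates$id, NULL))
  ok <- rep(TRUE, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    v <- tryCatch(embed_compound(candidates$smiles[i], compound_table),
                  error = function(e) NULL)
    if (is.null(v)) ok[i] <- FALSE else EC[i, ] <- v
  }
  if (any(!ok)) warn(sprintf("Dropped %d unembeddable candidate(s).", sum(!ok)))
  EC <- EC[ok, , drop = FALSE]
  expr <- t(safe_log(lines))
  out <- matrix(NA_real_, nrow(EC), ncol(lines),
                dimnames = list(rownames(EC), colnames(lines)))
  for (l in seq_len(ncol(lines))) {
    X <- cbind(matrix(expr[l, ], nrow(EC), ncol(expr), byrow = TRUE), EC)
    out[, l] <- predict_proba(model, X)
  }
  class(out) <- c("prediction_matrix", class(out))
  out
}

#' Filter molecules by predicted activity on required target lines
#'
#' Keeps molecules whose probability strictly exceeds `threshold` on every
#' named target line.
#'
#' @param matrix molecules-by-lines probability matrix.
#' @param target_lines column names that must all pass.
#' @param threshold strict probability cut (default 0.9).
#' @return Character vector of molecule ids (row order preserved).
#' @export
filter_by_target_lines <- function(matrix, target_lines, threshold = 0.9) {
  threshold <- check_scalar(threshold, "threshold", 0, 1)
  missing <- setdiff(target_lines, colnames(matrix))
  if (length(missing) > 0L) {
    abort(sprintf("Unknown line id(s): %s.", paste(missing, collapse = ", ")))
  }
  sub <- matrix[, target_lines, drop = FALSE]
  rownames(matrix)[apply(sub > threshold, 1L, all)]
}

#' Rank passing molecules by cell-line selectivity
#'
#' Among molecules passing [filter_by_target_lines()] on the required
#' lines, ranks ascending by the number of all lines on which the
#' probability strictly exceeds `threshold` (fewest lines = most
#' selective), breaking ties by the lower mean off-target probability and
#' then by molecule id; returns the first `top_n`.
#'
#' @param matrix molecules-by-lines probability matrix.
#' @param threshold strict probability cut.
#' @param required_lines target lines every kept molecule must hit.
#' @param top_n number of molecules to return.
#' @return Tibble `(molecule_id, n_lines_hit, mean_offtarget)` in rank
#'   order.
#' @export
selectivity_filter <- function(matrix, threshold, required_lines, top_n) {
  top_n <- check_count(top_n, "top_n")
  passing <- filter_by_target_lines(matrix, required_lines, threshold)
  if (length(passing) == 0L) {
    return(tibble(molecule_id = character(), n_lines_hit = integer(),
                  mean_offtarget = numeric()))
  }
  off <- setdiff(colnames(matrix), required_lines)
  sub <- matrix[passing, , drop = FALSE]
  tibble(
    molecule_id = passing,
    n_lines_hit = apply(sub > threshold, 1L, sum),
    mean_offtarget = if (length(off) > 0L)
      rowMeans(sub[, off, drop = FALSE]) else 0
  ) %>%
    arrange(.data$n_lines_hit, .data$mean_offtarget, .data$molecule_id) %>%
    slice_head(n = top_n)
}
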