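#' Rank genes by L1-regularized (Lasso) logistic regression
#'
#' Standardizes the features internally, fits a binomial Lasso path with
#' the penalty chosen by k-fold cross-validation, and ranks genes by the
#' absolute value of their coefficient at the selected penalty. Genes with
#' zero coefficients (or zero variance) never enter the ranking.
#'
#' @param features genes-by-samples or samples-by-genes matrix.
#' @param labels tibble from [binarize_outcome()] (or any tibble with the
#'   id column first and a `label` column).
#' @param folds CV folds for the penalty search.
#' @param seed integer seed (fixes the fold assignment).
#' @return A gene-ranking tibble `(gene, importance, rank)` sorted by
#'   non-increasing importance; attribute `method = "lasso"`. Empty (with a
#'   warning) when no coefficient survives.
#' @export
rank_features_lasso <- function(features, labels, folds = 5L, seed = 1L) {
  folds <- check_count(folds, "folds", min = 3L)
  ids <- labels[[1L]]
  X <- safe_log(align_features(features, ids))
  y <- labels$label
  keep <- apply(X, 2L, function(v) var(v) > 0)
  X <- X[, keep, drop = FALSE]
  Xs <- scale(X)
  foldid <- stratified_folds(y, folds, seed = derive_seed(seed, "lasso"))
  fit <- with_seed(derive_seed(seed, "glmnet"), glmnet::cv.glmnet(
    Xs, y, family = "binomial", foldid = foldid, standardize = FALSE))
  beta <- as.numeric(stats::coef(fit, s = "lambda.min"))[-1L]
  ranking <- tibble(gene = colnames(Xs), importance = abs(beta)) %>%
    filter(.data$importance > 0) %>%
    arrange(desc(.data$importance), .data$gene) %>%
    mutate(rank = row_number())
  if (nrow(ranking) == 0L) {
    warn("No gene survived the Lasso penalty; returning an empty ranking.")
  }
  attr(ranking, "method") <- "lasso"
  ranking
}

#' Rank genes by fold-aggregated permutation importance
#'
#' Model-agnostic alternative to [rank_features_lasso()]: the shared MLP is
#' trained per fold and each gene's held-out AUC drop under permutation is
#' averaged across folds.
#'
#' @inheritParams rank_features_lasso
#' @param arch [mlp_arch()] configuration.
#' @export
#' @param fitted optional trained `onco_classifier` on the same features;
#'   its fold models are reused instead of refitting.
rank_features_permutation <- function(features, labels, folds = 5L,
                                      arch = mlp_arch(), seed = 1L,
                                      fitted = NULL) {
  ids <- labels[[1L]]
  X <- safe_log(align_features(features, ids))
  y <- if (is.numeric(labels$label)) labels$label
       else as.integer(labels$label == "tumor")
  permutation_importance(X, y, folds = folds, arch = arch, seed = seed,
                         fitted = fitted)
}

#' Merge two endpoint gene rankings into one ordered target list
#'
#' Takes the top `top_k` genes of each ranking and orders their union by
#' the best (minimum) rank attained in either list; ties are broken by the
#' higher summed importance, then lexicographically.
#'
#' @param ranking_os,ranking_pfi gene-ranking tibbles.
#' @param top_k per-endpoint cut before merging (>= 1).
#' @return Tibble `(gene, best_rank, total_importance)` in merge order.
#' @export
merge_gene_lists <- function(ranking_os, ranking_pfi, top_k) {
  top_k <- check_count(top_k, "top_k")
  tops <- bind_rows(
    ranking_os %>% slice_head(n = top_k) %>% mutate(endpoint = "OS"),
    ranking_pfi %>% slice_head(n = top_k) %>% mutate(endpoint = "PFI")
  )
  tops %>%
    group_by(.data$gene) %>%
    summarise(best_rank = min(.data$rank),
              total_importance = sum(.data$importance),
              .groups = "drop") %>%
    arrange(.data$best_rank, desc(.data$total_importance), .data$gene)
}

#' Select discriminative genes from a ranking
#'
#' @param ranking gene-ranking tibble (non-empty).
#' @param top_k keep the first `top_k` genes; mutually exclusive with
#'   `min_importance`.
#' @param min_importance keep genes with importance >= this threshold.
#' @return Character vector of gene ids; attribute `selector` records the
#'   rule. A selector passing zero genes warns and returns an empty set.
#' @export
select_discriminative_genes <- function(ranking, top_k = NULL,
                                        min_importance = NULL) {
  if (nrow(ranking) == 0L) abort("`ranking` must be non-empty.")
  if (is.null(top_k) == is.null(min_importance)) {
    abort("Provide exactly one of `top_k` or `min_importance`.")
  }
  if (!is.null(top_k)) {
    sel <- ranking$gene[seq_len(min(check_count(top_k, "top_k"), nrow(ranking)))]
    rule <- sprintf("top_k=%d", top_k)
  } else {
    sel <- ranking$gene[ranking$importance >= min_importance]
    rule <- sprintf("importance>=%g", min_importance)
  }
  if (length(sel) == 0L) warn("Selector passed zero genes.")
  attr(sel, "selector") <- rule
  sel
}

#' Intersect the prognostic target list with the discriminative gene set
#'
#' Returns the subsequence of the prognostic list restricted to members of
#' the discriminative set; prognostic order is preserved.
#'
#' @param prognostic ordered character vector (or merged-ranking tibble with
#'   a `gene` column) of stage-1 genes.
#' @param discriminative character vector (or set) of stage-2 genes.
#' @return Character vector, ordered as in `prognostic`.
#' @export
intersect_targets <- function(prognostic, discriminative) {
  if (is.data.frame(prognostic)) prognostic <- prognostic$gene
  prognostic[prognostic %in% discriminative]
}
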