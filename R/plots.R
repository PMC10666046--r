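# ggplot2 views of the main result objects.

#' Plot per-fold cross-validated AUCs of a fitted classifier
#'
#' @param object an `onco_classifier`.
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.onco_classifier <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = factor(.data$fold), y = .data$auc)) +
    geom_col(fill = "steelblue") +
    geom_hline(yintercept = object$cv$mean_auc, linetype = 2) +
    geom_hline(yintercept = 0.5, colour = "grey50") +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "fold", y = "out-of-fold ROC AUC",
         title = sprintf("%s classifier: mean CV AUC %.3f",
                         object$stage, object$cv$mean_auc))
}

#' Boxplot-style view of positive vs all interaction scores
#'
#' Reproduces the diagnostic behind lower-quartile negative sampling: the
#' positive-pair score range should sit above the upper whisker of the
#' pooled distribution.
#'
#' @param object a `dpi_overlap_summary`.
#' @param ... ignored.
#' @export
autoplot.dpi_overlap_summary <- function(object, ...) {
  df <- object$summary
  ggplot(df, aes(x = .data$group)) +
    geom_boxplot(aes(ymin = .data$min, lower = .data$q1,
                     middle = .data$median, upper = .data$q3,
                     ymax = .data$max),
                 stat = "identity", width = 0.5, fill = "grey85") +
    geom_hline(yintercept = object$upper_whisker, linetype = 2,
               colour = "firebrick") +
    labs(x = NULL, y = "interaction score",
         title = sprintf("positive scores vs bulk (overlap: %s)",
                         object$overlap))
}

#' Heatmap of a molecules-by-lines prediction matrix
#'
#' @param object a `prediction_matrix` from [predict_matrix()].
#' @param ... ignored.
#' @export
autoplot.prediction_matrix <- function(object, ...) {
  m <- unclass(object)
  df <- as_tibble(m, rownames = "molecule") %>%
    tidyr::pivot_longer(-"molecule", names_to = "line",
                        values_to = "probability")
  ggplot(df, aes(x = .data$line, y = .data$molecule,
                 fill = .data$probability)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "darkred", limits = c(0, 1)) +
    theme(axis.text.x = element_blank(), axis.ticks.x = element_blank()) +
    labs(x = "cell line", y = "molecule", fill = "P(IC50)")
}

#' Lollipop plot of a gene ranking
#'
#' @param ranking a gene-ranking tibble.
#' @param top_n number of genes to show.
#' @export
plot_gene_ranking <- function(ranking, top_n = 20L) {
  df <- slice_head(ranking, n = top_n)
  ggplot(df, aes(x = .data$importance,
                 y = stats::reorder(.data$gene, .data$importance))) +
    geom_segment(aes(xend = 0, yend = stats::reorder(.data$gene,
                                                     .data$importance)),
                 colour = "grey60") +
    geom_point(colour = "steelblue", size = 2) +
    labs(x = "importance", y = NULL)
}
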