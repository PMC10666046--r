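# Stage 3: deterministic literature mining. Whole-token co-occurrence
# counting and gazetteer/pattern extraction of gene-inhibitor pairs. The
# module is fully deterministic: no randomness, no learned components.

whole_token_regex <- function(term) {
  paste0("(?<![[:alnum:]_])", escape_regex(term), "(?![[:alnum:]_])")
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.-])", "\\\\\\1", x)

contains_term <- function(texts, term) {
  stringr::str_detect(texts, stringr::regex(whole_token_regex(term),
                                            ignore_case = TRUE))
}

#' Count document-level gene-keyword co-occurrence
#'
#' Cell (gene, keyword) holds the number of documents containing both the
#' gene and the keyword under case-insensitive whole-token matching
#' (multi-word keywords match as a phrase). A `total_mentions` column sums
#' the keyword columns per gene, mirroring a per-query article-count table.
#'
#' @param corpus tibble `(id, text)` or a `syn_corpus`.
#' @param genes character vector of gene symbols.
#' @param keywords character vector of query keywords.
#' @return Tibble: `gene`, one count column per keyword, `total_mentions`.
#' @export
count_cooccurrence <- function(corpus, genes, keywords) {
  if (inherits(corpus, "syn_corpus")) corpus <- corpus$corpus
  stopifnot(length(genes) >= 1L, length(keywords) >= 1L)
  texts <- corpus$text
  gene_hit <- vapply(genes, function(g) contains_term(texts, g),
                     logical(length(texts)))
  if (length(texts) == 1L) gene_hit <- matrix(gene_hit, 1L)
  kw_hit <- vapply(keywords, function(w) contains_term(texts, w),
                   logical(length(texts)))
  if (length(texts) == 1L) kw_hit <- matrix(kw_hit, 1L)
  counts <- t(gene_hit) %*% kw_hit
  storage.mode(counts) <- "integer"
  out <- as_tibble(counts, .name_repair = "minimal")
  names(out) <- keywords
  out <- mutate(out, gene = genes, .before = 1L)
  out$total_mentions <- as.integer(unname(rowSums(counts)))
  out
}

#' Default inhibitor-name patterns for the gazetteer NER
#'
#' Tokens ending in the small-molecule-inhibitor suffixes (-nib as in
#' imatinib/vemurafenib/sunitinib, -ciclib, -parib, -zomib) and
#' development-code tokens (2-3 uppercase letters followed by 3-5 digits)
#' are treated as inhibitor names.
#'
#' @return Character vector of regular expressions.
#' @export
inhibitor_patterns <- function() {
  c(suffix = "\\b[a-zA-Z]{3,}(?:nib|ciclib|parib|zomib)\\b",
    code = "\\b[A-Z]{2,3}[0-9]{3,5}\\b")
}

#' Extract gene-inhibitor pairs from a corpus
#'
#' Deterministic gazetteer/pattern named-entity recognition: within each
#' sentence, genes are matched against the lexicon (case-insensitive whole
#' tokens) and inhibitors against an optional lexicon plus suffix/code
#' patterns; every (gene, inhibitor) pair co-occurring in a sentence is
#' reported with its evidence span.
#'
#' @param corpus tibble `(id, text)` or a `syn_corpus`.
#' @param gene_lexicon character vector of gene symbols (non-empty).
#' @param inhibitor_lexicon optional character vector of known inhibitor
#'   names.
#' @param patterns regular expressions for inhibitor-like tokens
#'   (default [inhibitor_patterns()]).
#' @return Tibble `(doc_id, gene, inhibitor, sentence)`.
#' @export
extract_pairs <- function(corpus, gene_lexicon, inhibitor_lexicon = NULL,
                          patterns = inhibitor_patterns()) {
  if (inherits(corpus, "syn_corpus")) corpus <- corpus$corpus
  if (length(gene_lexicon) == 0L) abort("`gene_lexicon` must be non-empty.")
  out <- list()
  for (d in seq_len(nrow(corpus))) {
    sentences <- strsplit(corpus$text[d], "(?<=[.!?])\\s+", perl = TRUE)[[1L]]
    for (s in sentences) {
      genes <- unique(gene_lexicon[vapply(gene_lexicon, function(g)
        contains_term(s, g), logical(1))])
      if (length(genes) == 0L) next
      inhibitors <- character(0)
      if (!is.null(inhibitor_lexicon)) {
        inhibitors <- inhibitor_lexicon[vapply(inhibitor_lexicon, function(i)
          contains_term(s, i), logical(1))]
      }
      for (p in patterns) {
        inhibitors <- c(inhibitors,
                        stringr::str_extract_all(s, stringr::regex(p))[[1L]])
      }
      inhibitors <- setdiff(unique(inhibitors), genes)
      if (length(inhibitors) == 0L) next
      out[[length(out) + 1L]] <- tidyr::expand_grid(
        doc_id = corpus$id[d], gene = genes, inhibitor = inhibitors) %>%
        mutate(sentence = s)
    }
  }
  if (length(out) == 0L) {
    return(tibble(doc_id = character(), gene = character(),
                  inhibitor = character(), sentence = character()))
  }
  distinct(bind_rows(out), .data$doc_id, .data$gene, .data$inhibitor,
           .keep_all = TRUE)
}

#' Append the per-gene inhibitor list to a co-occurrence table
#'
#' @param table output of [count_cooccurrence()].
#' @param pairs output of [extract_pairs()].
#' @return The table with an `inhibitors` column: the deduplicated,
#'   alphabetized, comma-separated inhibitor list per gene.
#' @export
attach_inhibitor_column <- function(table, pairs) {
  lists <- pairs %>%
    distinct(.data$gene, .data$inhibitor) %>%
    group_by(.data$gene) %>%
    summarise(inhibitors = paste(sort(unique(.data$inhibitor)),
                                 collapse = ", "), .groups = "drop")
  table %>%
    left_join(lists, by = "gene") %>%
    mutate(inhibitors = ifelse(is.na(.data$inhibitors), "", .data$inhibitors))
}
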