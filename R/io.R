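# Plain-text writers/readers for every pipeline artifact. All formats are
# line-oriented text so runs are diffable and digest-stable.

#' Expression matrix TSV (genes as rows, header = sample ids)
#' @param matrix genes-by-samples numeric matrix.
#' @param path file path.
#' @export
write_expression_tsv <- function(matrix, path) {
  df <- data.frame(gene = rownames(matrix), matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, comment.char = "")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene
  m
}

#' Clinical table CSV
#' @param clinical tibble with patient_id, os_time, os_event, pfi_time,
#'   pfi_event.
#' @param path file path.
#' @export
write_clinical_csv <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_clinical_csv
#' @export
read_clinical_csv <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Protein FASTA
#' @param proteins tibble `(id, sequence)`.
#' @param path file path.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(set, path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  tibble(id = names(set), sequence = as.character(set))
}

#' SMILES library (one `SMILES<TAB>id` per line)
#' @param compounds tibble `(id, smiles)`.
#' @param path file path.
#' @export
write_smiles <- function(compounds, path) {
  writeLines(paste(compounds$smiles, compounds$id, sep = "\t"), path)
}

#' @rdname write_smiles
#' @export
read_smiles <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(id = vapply(parts, `[`, character(1), 2L),
         smiles = vapply(parts, `[`, character(1), 1L))
}

#' Interaction score table TSV (compound_id, protein_id, score)
#' @param scores tibble `(compound_id, protein_id, score)`.
#' @param path file path.
#' @export
write_scores_tsv <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_scores_tsv
#' @export
read_scores_tsv <- function(path) {
  as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE))
}

#' Literature corpus JSONL (one `{"id": ..., "text": ...}` per line)
#' @param corpus tibble `(id, text)` or a `syn_corpus`.
#' @param path file path.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  if (inherits(corpus, "syn_corpus")) corpus <- corpus$corpus
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(list(id = corpus$id[i], text = corpus$text[i]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(l) jsonlite::fromJSON(l))
  tibble(id = vapply(rows, `[[`, character(1), "id"),
         text = vapply(rows, `[[`, character(1), "text"))
}
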