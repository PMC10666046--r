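#' Normalize an expression matrix to a housekeeping reference gene
#'
#' Divides each sample's column by that sample's reference-gene value, the
#' standard housekeeping normalization (e.g. to GAPDH). The reference row
#' becomes all ones and the operation is idempotent.
#'
#' @param matrix numeric genes-by-samples matrix with unique rownames.
#' @param reference_gene rowname of the reference gene; must be strictly
#'   positive in every sample.
#' @return The normalized matrix; attribute `normalized_to` records the
#'   reference gene.
#' @examples
#' m <- matrix(c(2, 4, 4, 4), 2, dimnames = list(c("REF", "T"), c("s1", "s2")))
#' normalize_expression(m, "REF")["T", ]
#' @export
normalize_expression <- function(matrix, reference_gene) {
  if (!reference_gene %in% rownames(matrix)) {
    abort(sprintf("Reference gene '%s' not found in the matrix.",
                  reference_gene))
  }
  ref <- matrix[reference_gene, ]
  bad <- colnames(matrix)[!is.finite(ref) | ref <= 0]
  if (length(bad) > 0L) {
    abort(sprintf(
      "Reference gene '%s' is zero or non-finite in sample(s): %s.",
      reference_gene, paste(bad, collapse = ", ")))
  }
  out <- sweep(matrix, 2L, ref, "/")
  attr(out, "normalized_to") <- reference_gene
  out
}

#' Binarize a survival endpoint at the cohort median
#'
#' The label is 1 iff the patient's endpoint time strictly exceeds the
#' median computed over all included patients; patients exactly at the
#' median are assigned per `tie_rule` (default `"below"`, label 0).
#'
#' @param clinical tibble with `patient_id` and `<endpoint>_time` columns.
#' @param endpoint `"os"` or `"pfi"`.
#' @param tie_rule `"below"` (ties get label 0) or `"above"`.
#' @return Tibble with `patient_id`, `label`; attributes `endpoint` and
#'   `median_used`.
#' @export
binarize_outcome <- function(clinical, endpoint = c("os", "pfi"),
                             tie_rule = c("below", "above")) {
  endpoint <- match.arg(endpoint)
  tie_rule <- match.arg(tie_rule)
  col <- paste0(endpoint, "_time")
  if (!col %in% names(clinical)) {
    abort(sprintf("Column '%s' missing from the clinical table.", col))
  }
  times <- clinical[[col]]
  keep <- is.finite(times)
  if (sum(keep) < 2L) abort("Need at least 2 patients with finite times.")
  times <- times[keep]
  med <- median(times)
  if (all(times == times[1L])) {
    abort("All endpoint times identical: median split is degenerate.")
  }
  label <- if (tie_rule == "below") as.integer(times > med)
           else as.integer(times >= med)
  if (length(unique(label)) < 2L) {
    abort("Median split produced a single class; check the time distribution.")
  }
  out <- tibble(patient_id = clinical$patient_id[keep], label = label)
  attr(out, "endpoint") <- toupper(endpoint)
  attr(out, "median_used") <- med
  out
}
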