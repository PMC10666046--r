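#' Generate a synthetic patient cohort with planted prognostic genes
#'
#' Draws a genes-by-patients expression matrix (log-normal) and a clinical
#' table with overall-survival (OS) and progression-free-interval (PFI)
#' times. Event times are exponential with a log-rate equal to a linear
#' combination of the planted genes' standardized log-expression scaled by
#' `effect_size`, so higher planted expression shortens survival. With
#' `effect_size = 0` no gene is associated with outcome.
#'
#' The first gene (`G0001`) is a designated low-variance housekeeping gene,
#' never planted, intended as the reference for [normalize_expression()];
#' its id is recorded in the `reference_gene` attribute of the expression
#' matrix.
#'
#' @param n_patients number of patients (>= 4).
#' @param n_genes number of genes (rows).
#' @param n_prognostic number of planted prognostic genes (<= `n_genes`).
#' @param effect_size non-negative scale of the planted log-hazard signal.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param censoring_fraction expected fraction of administratively censored
#'   patients (default 0: all events observed).
#' @param baseline_os,baseline_pfi baseline mean event times in days.
#' @return A `syn_cohort` list with elements `expression` (matrix, genes x
#'   patients), `clinical` (tibble: patient_id, os_time, os_event, pfi_time,
#'   pfi_event), `planted_prognostic_genes`, `effect_size`, `seed`.
#' @examples
#' co <- generate_cohort(60, 40, 5, effect_size = 1, seed = 1)
#' dim(co$expression)
#' @export
generate_cohort <- function(n_patients, n_genes, n_prognostic, effect_size,
                            seed, censoring_fraction = 0,
                            baseline_os = 730, baseline_pfi = 365) {
  n_patients <- check_count(n_patients, "n_patients", min = 4L)
  n_genes <- check_count(n_genes, "n_genes", min = 2L)
  n_prognostic <- check_count(n_prognostic, "n_prognostic", min = 0L)
  effect_size <- check_scalar(effect_size, "effect_size", min = 0)
  censoring_fraction <- check_scalar(censoring_fraction,
                                     "censoring_fraction", 0, 0.95)
  if (n_prognostic > n_genes - 1L) {
    abort("`n_prognostic` must leave at least the reference gene unplanted.")
  }
  genes <- sprintf("G%04d", seq_len(n_genes))
  patients <- sprintf("P%05d", seq_len(n_patients))

  with_seed(seed, {
    meanlog <- rnorm(n_genes, mean = 3, sd = 0.7)
    sdlog <- rep(0.8, n_genes)
    sdlog[1L] <- 0.05 # housekeeping reference
    logx <- matrix(rnorm(n_genes * n_patients), n_genes, n_patients)
    logx <- logx * sdlog + meanlog
    expr <- exp(logx)
    dimnames(expr) <- list(genes, patients)

    planted <- if (n_prognostic > 0L) {
      sort(sample(genes[-1L], n_prognostic))
    } else {
      character(0)
    }

    lp <- rep(0, n_patients)
    if (n_prognostic > 0L && effect_size > 0) {
      z <- scale(t(logx[match(planted, genes), , drop = FALSE]))
      lp <- effect_size * rowSums(z) / sqrt(n_prognostic)
    }
    os_time <- rexp(n_patients, rate = exp(lp) / baseline_os)
    pfi_time <- rexp(n_patients, rate = exp(lp) / baseline_pfi)
    os_event <- rep(1L, n_patients)
    pfi_event <- rep(1L, n_patients)
    if (censoring_fraction > 0) {
      cens <- runif(n_patients) < censoring_fraction
      u <- runif(n_patients)
      os_time[cens] <- os_time[cens] * u[cens]
      pfi_time[cens] <- pfi_time[cens] * u[cens]
      os_event[cens] <- 0L
      pfi_event[cens] <- 0L
    }
    os_time <- pmax(os_time, 1e-3)
    pfi_time <- pmax(pfi_time, 1e-3)

    attr(expr, "reference_gene") <- genes[1L]
    structure(
      list(
        expression = expr,
        clinical = tibble(
          patient_id = patients,
          os_time = os_time, os_event = os_event,
          pfi_time = pfi_time, pfi_event = pfi_event
        ),
        planted_prognostic_genes = planted,
        effect_size = effect_size,
        seed = seed
      ),
      class = "syn_cohort"
    )
  })
}

#' Generate a synthetic tumor/normal tissue panel
#'
#' Log-normal expression with `n_discriminative` planted genes whose tumor
#' mean is shifted by `shift` on the log scale; all other genes are
#' exchangeable between classes. `shift = 0` plants no usable signal.
#'
#' @param n_tumor,n_normal class sizes (both >= 1).
#' @param n_genes number of genes, ignored when `gene_ids` is given.
#' @param n_discriminative number of planted discriminative genes.
#' @param shift log-scale mean shift applied to planted genes in tumors.
#' @param seed integer seed.
#' @param gene_ids optional gene-id vector (e.g. a cohort's rownames) so the
#'   panel shares a namespace with stage-1 data.
#' @param planted_genes optional explicit planted set (must be in the gene
#'   ids); used to plant the same genes in cohort and panel.
#' @return A `syn_tissue_panel` list: `expression` (genes x samples),
#'   `labels` (tibble: sample_id, label in {tumor, normal}),
#'   `planted_discriminative_genes`, `shift`, `seed`.
#' @export
generate_tissue_panel <- function(n_tumor, n_normal, n_genes,
                                  n_discriminative, shift, seed,
                                  gene_ids = NULL, planted_genes = NULL) {
  n_tumor <- check_count(n_tumor, "n_tumor", min = 1L)
  n_normal <- check_count(n_normal, "n_normal", min = 1L)
  shift <- check_scalar(shift, "shift")
  genes <- gene_ids %||% sprintf("G%04d", seq_len(check_count(n_genes, "n_genes")))
  n_genes <- length(genes)
  n_discriminative <- check_count(n_discriminative, "n_discriminative", min = 0L)
  if (n_discriminative > n_genes) {
    abort("`n_discriminative` must not exceed the number of genes.")
  }
  n <- n_tumor + n_normal
  samples <- sprintf("S%05d", seq_len(n))
  lab <- c(rep("tumor", n_tumor), rep("normal", n_normal))

  with_seed(seed, {
    if (is.null(planted_genes)) {
      planted <- if (n_discriminative > 0L) sort(sample(genes, n_discriminative))
                 else character(0)
    } else {
      stopifnot(all(planted_genes %in% genes))
      planted <- sort(planted_genes)
    }
    meanlog <- rnorm(n_genes, mean = 3, sd = 0.7)
    logx <- matrix(rnorm(n_genes * n), n_genes, n) * 0.8 + meanlog
    if (length(planted) > 0L && shift != 0) {
      idx <- match(planted, genes)
      logx[idx, lab == "tumor"] <- logx[idx, lab == "tumor"] + shift
    }
    expr <- exp(logx)
    dimnames(expr) <- list(genes, samples)
    structure(
      list(
        expression = expr,
        labels = tibble(sample_id = samples, label = lab),
        planted_discriminative_genes = planted,
        shift = shift,
        seed = seed
      ),
      class = "syn_tissue_panel"
    )
  })
}
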