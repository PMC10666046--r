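# End-to-end orchestration: config schema, synthetic presets, staged run.

#' Default pipeline configuration
#'
#' Two-level list of per-stage parameter blocks. Every entry can be
#' overridden from a YAML file via [validate_config()]; unknown keys are
#' rejected and range violations are reported exhaustively.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 42L,
    cohort = list(n_patients = 600L, n_genes = 120L, n_prognostic = 10L,
                  effect_size = 2.0, censoring_fraction = 0),
    targets = list(folds = 5L, top_k = 25L, n_synthetic = 2000L,
                   hidden = 12L, decay = 0.01, maxit = 120L),
    tissue = list(n_tumor = 420L, n_normal = 180L, shift = 2.0,
                  select_top_k = 40L),
    litmine = list(enabled = TRUE, n_docs = 300L,
                   keywords = c("target", "cancer", "lung cancer", "phase",
                                "drug", "approval", "FDA")),
    embeddings = list(d = 100L, window = 5L, k = 3L, radius = 1L),
    world = list(n_proteins = 50L, n_compounds = 250L, pos_fraction = 0.1,
                 protein_tilt = 0.85, compound_tilt = 1.1),
    dpi = list(folds = 5L, screen_threshold = 0.95, n_candidates = 400L),
    preclinical = list(n_lines = 60L, n_compounds = 72L,
                       n_driver_genes = 20L, gain = 12, coverage = 0.88,
                       threshold = 0.9, top_n = 5L, n_required_lines = 2L,
                       hidden = 16L, maxit = 200L)
  )
}

#' Validate (and default-fill) a pipeline configuration
#'
#' @param config a path to a YAML file, a named list of overrides, or
#'   `NULL` (defaults only).
#' @return The resolved configuration (defaults filled). All schema
#'   violations -- unknown keys, type mismatches, out-of-range values --
#'   are collected and reported together.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config) %||% list()
  }
  config <- config %||% list()
  if (!is.list(config)) abort("Config must be a named list or YAML mapping.")
  base <- default_config()
  errors <- character(0)

  unknown_top <- setdiff(names(config), names(base))
  if (length(unknown_top) > 0L) {
    errors <- c(errors, sprintf("unknown block(s): %s",
                                paste(unknown_top, collapse = ", ")))
  }
  for (blk in intersect(names(config), names(base))) {
    if (!is.list(base[[blk]])) {
      base[[blk]] <- config[[blk]]
      next
    }
    if (!is.list(config[[blk]])) {
      errors <- c(errors, sprintf("block '%s' must be a mapping", blk))
      next
    }
    unknown <- setdiff(names(config[[blk]]), names(base[[blk]]))
    if (length(unknown) > 0L) {
      errors <- c(errors, sprintf("unknown key(s) in '%s': %s", blk,
                                  paste(unknown, collapse = ", ")))
    }
    for (k in intersect(names(config[[blk]]), names(base[[blk]]))) {
      base[[blk]][[k]] <- config[[blk]][[k]]
    }
  }

  rng <- function(blk, key, lo, hi) {
    v <- base[[blk]][[key]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < lo) || any(v > hi)) {
      errors <<- c(errors, sprintf("%s.%s must be in [%s, %s]",
                                   blk, key, format(lo), format(hi)))
    }
  }
  rng("world", "pos_fraction", 1e-9, 0.499999)
  rng("dpi", "screen_threshold", 0, 1)
  rng("preclinical", "threshold", 0, 1)
  rng("preclinical", "coverage", 0.05, 1)
  rng("cohort", "effect_size", 0, Inf)
  rng("cohort", "censoring_fraction", 0, 0.95)
  for (blk in c("cohort", "tissue", "world", "dpi", "preclinical",
                "targets")) {
    for (k in names(base[[blk]])) {
      v <- base[[blk]][[k]]
      if (grepl("^n_|^top_|folds|hidden|maxit", k) && k != "n_required_lines") {
        if (!is.numeric(v) || length(v) != 1L || v < 0 || v != floor(v)) {
          errors <- c(errors, sprintf("%s.%s must be a non-negative integer",
                                      blk, k))
        }
      }
    }
  }
  if (length(errors) > 0L) {
    abort(paste0("Invalid configuration:\n",
                 paste(" -", errors, collapse = "\n")))
  }
  base
}

#' Synthetic preset overrides
#'
#' `"strong"` is the default study condition (planted signal recoverable by
#' every stage); `"weak"` halves the planted effects; `"null"` removes all
#' planted signal (calibration runs).
#'
#' @param name preset name.
#' @return Config override list for [validate_config()].
#' @export
synth_preset <- function(name = c("strong", "weak", "null")) {
  name <- match.arg(name)
  switch(name,
    strong = list(),
    weak = list(cohort = list(effect_size = 1.0),
                tissue = list(shift = 1.0),
                world = list(protein_tilt = 0.45, compound_tilt = 0.55),
                preclinical = list(gain = 6)),
    null = list(cohort = list(effect_size = 0),
                tissue = list(shift = 0),
                world = list(protein_tilt = 0, compound_tilt = 0),
                preclinical = list(n_driver_genes = 0L))
  )
}

merge_config <- function(base, override) {
  for (blk in names(override)) {
    if (is.list(override[[blk]])) {
      for (k in names(override[[blk]])) base[[blk]][[k]] <- override[[blk]][[k]]
    } else {
      base[[blk]] <- override[[blk]]
    }
  }
  base
}

#' Run the five-stage pipeline end to end on synthetic data
#'
#' Stages run in order: prognostic target identification, tumor/normal
#' filtering, literature mining (optional), drug-protein interaction
#' training + screening, preclinical IC50 emulation + selectivity
#' filtering. Every stage derives its own seed from the global seed, each
#' stage's outputs are written before the next starts, and identical
#' config + seed yields identical file digests.
#'
#' @param config config list or YAML path (see [validate_config()]).
#' @param synth synthetic preset (`"strong"`, `"weak"`, `"null"`).
#' @param seed global seed (overrides the config seed when given).
#' @param out_dir output directory (created if needed; default a fresh
#'   temporary directory).
#' @return A `run_report` list: per-stage metrics, gene lists, hit counts,
#'   the final molecule list, file digests and elapsed times.
#' @export
run_pipeline <- function(config = NULL, synth = "strong", seed = NULL,
                         out_dir = NULL) {
  cfg <- validate_config(config)
  cfg <- merge_config(cfg, synth_preset(synth))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  out_dir <- out_dir %||% tempfile("oncodisco_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = cfg$seed, preset = synth, config = cfg,
                 stages = list())
  t_all <- proc.time()[["elapsed"]]
  sseed <- function(label) derive_seed(cfg$seed, label)

  ## Stage 1: prognostic targets ------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  co <- generate_cohort(cfg$cohort$n_patients, cfg$cohort$n_genes,
                        cfg$cohort$n_prognostic, cfg$cohort$effect_size,
                        seed = sseed("cohort"),
                        censoring_fraction = cfg$cohort$censoring_fraction)
  expr <- normalize_expression(co$expression,
                               attr(co$expression, "reference_gene"))
  write_expression_tsv(expr, file.path(out_dir, "expression.tsv"))
  write_clinical_csv(co$clinical, file.path(out_dir, "clinical.csv"))
  arch <- mlp_arch(cfg$targets$hidden, cfg$targets$decay, cfg$targets$maxit)
  rankings <- list()
  aucs <- list()
  for (ep in c("os", "pfi")) {
    labels <- binarize_outcome(co$clinical, ep)
    clf <- train_outcome_classifier(expr, labels, folds = cfg$targets$folds,
                                    arch = arch,
                                    seed = sseed(paste0("clf_", ep)))
    aucs[[ep]] <- clf$cv$mean_auc
    rankings[[ep]] <- rank_features_lasso(expr, labels,
                                          folds = cfg$targets$folds,
                                          seed = sseed(paste0("lasso_", ep)))
    readr::write_csv(
      mutate(rankings[[ep]], endpoint = toupper(ep)),
      file.path(out_dir, sprintf("ranking_%s.csv", ep)))
  }
  prognostic <- merge_gene_lists(rankings$os, rankings$pfi,
                                 top_k = cfg$targets$top_k)
  readr::write_csv(prognostic, file.path(out_dir, "prognostic_targets.csv"))
  report$stages$targets <- list(
    n_patients = cfg$cohort$n_patients,
    cv_auc_os = aucs$os, cv_auc_pfi = aucs$pfi,
    planted = co$planted_prognostic_genes,
    n_prognostic = nrow(prognostic),
    genes = prognostic$gene,
    elapsed = proc.time()[["elapsed"]] - t0)

  ## Stage 2: tumor/normal filter -----------------------------------------
  t0 <- proc.time()[["elapsed"]]
  panel <- generate_tissue_panel(
    cfg$tissue$n_tumor, cfg$tissue$n_normal, cfg$cohort$n_genes,
    n_discriminative = cfg$cohort$n_prognostic, shift = cfg$tissue$shift,
    seed = sseed("tissue"), gene_ids = rownames(co$expression),
    planted_genes = if (cfg$tissue$shift == 0) NULL else
      co$planted_prognostic_genes)
  tis <- train_tissue_classifier(panel$expression, panel$labels,
                                 arch = arch, seed = sseed("tissue_clf"))
  tis_rank <- rank_features_permutation(
    panel$expression, panel$labels,
    arch = arch, seed = sseed("tissue_imp"), fitted = tis)
  discriminative <- select_discriminative_genes(
    tis_rank, top_k = cfg$tissue$select_top_k)
  final_targets <- intersect_targets(prognostic, discriminative)
  readr::write_csv(tibble(gene = final_targets),
                   file.path(out_dir, "final_targets.csv"))
  report$stages$filter <- list(
    cv_auc = tis$cv$mean_auc, n_discriminative = length(discriminative),
    n_final_targets = length(final_targets), genes = final_targets,
    elapsed = proc.time()[["elapsed"]] - t0)
  if (length(final_targets) == 0L) {
    # keep downstream stages exercised even if the intersection is empty
    final_targets <- head(prognostic$gene, 5L)
    report$stages$filter$note <- "empty intersection; fell back to top prognostic genes"
  }

  ## Stage 3: literature mining -------------------------------------------
  if (isTRUE(cfg$litmine$enabled)) {
    t0 <- proc.time()[["elapsed"]]
    inhibitors <- c("soratinib", "velatinib", "AZD4547", "lorbrenib",
                    "PF06873", "crizatinib")
    corp <- generate_corpus(final_targets, inhibitors,
                            cfg$litmine$keywords, cfg$litmine$n_docs,
                            seed = sseed("corpus"))
    write_corpus_jsonl(corp, file.path(out_dir, "corpus.jsonl"))
    tab <- count_cooccurrence(corp, final_targets, cfg$litmine$keywords)
    pairs <- extract_pairs(corp, final_targets,
                           inhibitor_lexicon = inhibitors)
    tab <- attach_inhibitor_column(tab, pairs)
    readr::write_csv(tab, file.path(out_dir, "litmine_table.csv"))
    report$stages$litmine <- list(
      n_docs = cfg$litmine$n_docs, n_pairs = nrow(pairs),
      elapsed = proc.time()[["elapsed"]] - t0)
  } else {
    report$stages$litmine <- list(skipped = TRUE)
  }

  ## Stage 4: drug-protein interactions -----------------------------------
  t0 <- proc.time()[["elapsed"]]
  prot <- generate_proteins(cfg$world$n_proteins, seed = sseed("proteins"),
                            tilt = cfg$world$protein_tilt)
  # the first proteins encode the final target genes
  n_map <- min(length(final_targets), nrow(prot))
  prot$id[seq_len(n_map)] <- final_targets[seq_len(n_map)]
  rownames(attr(prot, "latents")) <- prot$id
  cmp <- generate_compounds(cfg$world$n_compounds, seed = sseed("compounds"),
                            tilt = cfg$world$compound_tilt)
  world <- generate_interaction_world(prot, cmp,
                                      pos_fraction = cfg$world$pos_fraction,
                                      seed = sseed("world"))
  write_fasta(prot, file.path(out_dir, "proteins.fasta"))
  write_smiles(cmp, file.path(out_dir, "library.smi"))
  write_scores_tsv(world$score_table, file.path(out_dir, "scores.tsv"))

  ptab <- train_token_embedding(
    protein_corpus(prot, k = cfg$embeddings$k),
    d = cfg$embeddings$d, window = cfg$embeddings$window,
    seed = sseed("ptab"), kind = "aa_3mer", k = cfg$embeddings$k)
  ctab <- train_token_embedding(
    compound_corpus(cmp, radius = cfg$embeddings$radius),
    d = cfg$embeddings$d, window = cfg$embeddings$window,
    seed = sseed("ctab"), kind = "substructure_id",
    radius = cfg$embeddings$radius)
  write_embedding_table(ptab, file.path(out_dir, "protein_embedding.tsv"))
  write_embedding_table(ctab, file.path(out_dir, "compound_embedding.tsv"))

  ov <- positive_overlap_summary(world$score_table, world$positive_pairs)
  EP <- embed_proteins_matrix(prot, ptab)
  EC <- embed_compounds_matrix(cmp, ctab)
  ds <- assemble_dpi_dataset(world$positive_pairs, world$score_table,
                             protein_vectors = EP, compound_vectors = EC)
  dpi_model <- train_dpi_model(ds, folds = cfg$dpi$folds, arch = arch,
                               seed = sseed("dpi"))
  candidates <- generate_compounds(cfg$dpi$n_candidates,
                                   seed = sseed("candidates"),
                                   tilt = cfg$world$compound_tilt)
  target_prot <- prot[seq_len(n_map), , drop = FALSE]
  hits <- screen_library(dpi_model, target_prot, candidates, ptab, ctab,
                         threshold = cfg$dpi$screen_threshold)
  readr::write_csv(hits, file.path(out_dir, "dpi_hits.csv"))
  readr::write_csv(tally_hits_per_gene(hits),
                   file.path(out_dir, "hits_per_gene.csv"))
  report$stages$dpi <- list(
    n_pairs = nrow(ds), n_positive = sum(ds$label == 1L),
    n_negative = sum(ds$label == 0L), cv_auc = dpi_model$cv$mean_auc,
    score_overlap = ov$overlap, n_hits = nrow(hits),
    elapsed = proc.time()[["elapsed"]] - t0)

  ## Stage 5: preclinical emulation ---------------------------------------
  t0 <- proc.time()[["elapsed"]]
  panel_compounds <- cmp[seq_len(min(cfg$preclinical$n_compounds,
                                     nrow(cmp))), , drop = FALSE]
  attr(panel_compounds, "latents") <-
    attr(cmp, "latents")[seq_len(nrow(panel_compounds)), , drop = FALSE]
  sens <- generate_sensitivity_panel(
    rownames(co$expression), panel_compounds,
    n_lines = cfg$preclinical$n_lines, seed = sseed("sens"),
    n_driver_genes = cfg$preclinical$n_driver_genes,
    gain = cfg$preclinical$gain, coverage = cfg$preclinical$coverage)
  EC_panel <- EC[panel_compounds$id, , drop = FALSE]
  cell_ds <- assemble_cell_dataset(sens$lines, sens$sensitivity, EC_panel)
  ic50_arch <- mlp_arch(cfg$preclinical$hidden, cfg$targets$decay,
                        cfg$preclinical$maxit)
  ic50 <- train_ic50_model(cell_ds, arch = ic50_arch, seed = sseed("ic50"))

  # candidate set: screened hit compounds plus their ring-system fragments
  hit_cmp <- candidates %>% filter(.data$id %in% unique(hits$compound_id))
  frags <- character(0)
  for (i in seq_len(nrow(hit_cmp))) {
    f <- decompose_molecule(hit_cmp$smiles[i])
    frags <- c(frags, setdiff(f, hit_cmp$smiles[i]))
  }
  frags <- unique(frags)
  cand_tbl <- bind_rows(
    hit_cmp %>% select("id", "smiles"),
    if (length(frags) > 0L)
      tibble(id = sprintf("FRAG%04d", seq_along(frags)), smiles = frags)
  )
  report$stages$preclinical <- list(cv_auc = ic50$cv$mean_auc,
                                    n_importance_genes = nrow(ic50$gene_ranking),
                                    n_candidates = nrow(cand_tbl),
                                    n_fragments = length(frags))
  if (nrow(cand_tbl) > 0L) {
    pm <- predict_matrix(ic50, cand_tbl, sens$lines, ctab)
    required <- colnames(sens$lines)[seq_len(cfg$preclinical$n_required_lines)]
    sel <- selectivity_filter(pm, cfg$preclinical$threshold, required,
                              top_n = cfg$preclinical$top_n)
    utils::write.table(
      data.frame(molecule = rownames(pm), round(pm, 6), check.names = FALSE),
      file.path(out_dir, "prediction_matrix.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    readr::write_csv(sel, file.path(out_dir, "selected_molecules.csv"))
    report$stages$preclinical$required_lines <- required
    report$stages$preclinical$final_molecules <- sel$molecule_id
  } else {
    report$stages$preclinical$final_molecules <- character(0)
  }
  report$stages$preclinical$elapsed <- proc.time()[["elapsed"]] - t0

  ## report -----------------------------------------------------------------
  files <- sort(list.files(out_dir, full.names = TRUE))
  files <- files[!basename(files) %in% "report.json"]
  digests <- tools::md5sum(files)
  names(digests) <- basename(names(digests))
  report$digests <- as.list(digests)
  report$elapsed <- proc.time()[["elapsed"]] - t_all
  report$out_dir <- out_dir
  jsonlite::write_json(
    report[setdiff(names(report), "config")],
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = 10)
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report: seed %d, preset '%s'>\n", x$seed, x$preset))
  cat(sprintf("  stage 1 targets:  CV AUC OS %.3f / PFI %.3f, %d genes\n",
              x$stages$targets$cv_auc_os, x$stages$targets$cv_auc_pfi,
              x$stages$targets$n_prognostic))
  cat(sprintf("  stage 2 filter:   CV AUC %.3f, %d final targets\n",
              x$stages$filter$cv_auc, x$stages$filter$n_final_targets))
  if (!isTRUE(x$stages$litmine$skipped)) {
    cat(sprintf("  stage 3 litmine:  %d extracted pairs\n",
                x$stages$litmine$n_pairs))
  }
  cat(sprintf("  stage 4 DPI:      CV AUC %.3f, %d hits\n",
              x$stages$dpi$cv_auc, x$stages$dpi$n_hits))
  cat(sprintf("  stage 5 IC50:     CV AUC %.3f, %d final molecules\n",
              x$stages$preclinical$cv_auc,
              length(x$stages$preclinical$final_molecules)))
  cat(sprintf("  elapsed: %.1f s   out: %s\n", x$elapsed, x$out_dir))
  invisible(x)
}
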