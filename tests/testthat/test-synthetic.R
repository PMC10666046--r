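# Synthetic-data module: determinism, planted structure, argument guards.

test_that("all generators are byte-identical under a fixed seed", {
  gens <- list(
    cohort = function() generate_cohort(30, 20, 3, 1.0, seed = 11),
    tissue = function() generate_tissue_panel(15, 10, 25, 4, 1.5, seed = 12),
    proteins = function() generate_proteins(8, c(30, 60), seed = 13),
    compounds = function() generate_compounds(15, seed = 14),
    corpus = function() generate_corpus(c("KRAS", "TP53"), c("zotinib"),
                                        c("cancer"), 20, seed = 15)
  )
  for (nm in names(gens)) {
    expect_identical(gens[[nm]](), gens[[nm]](), label = nm)
  }
  prot <- generate_proteins(6, c(30, 50), seed = 1)
  cmp <- generate_compounds(20, seed = 2)
  expect_identical(generate_interaction_world(prot, cmp, 0.1, seed = 3),
                   generate_interaction_world(prot, cmp, 0.1, seed = 3))
  expect_identical(
    generate_sensitivity_panel(letters, cmp, n_lines = 10, seed = 4),
    generate_sensitivity_panel(letters, cmp, n_lines = 10, seed = 4))
})

test_that("cohort has the requested shape, planted genes and positive times", {
  co <- generate_cohort(80, 60, 6, 1.5, seed = 7)
  expect_equal(dim(co$expression), c(60, 80))
  expect_length(co$planted_prognostic_genes, 6)
  expect_true(all(co$planted_prognostic_genes %in% rownames(co$expression)))
  expect_false(attr(co$expression, "reference_gene") %in%
                 co$planted_prognostic_genes)
  expect_true(all(co$expression > 0))
  expect_true(all(co$clinical$os_time > 0))
  expect_true(all(co$clinical$pfi_time > 0))
  expect_false(any(duplicated(co$clinical$patient_id)))
})

test_that("planted effect drives survival and vanishes at effect 0", {
  co1 <- generate_cohort(400, 30, 5, 2.0, seed = 21)
  lab1 <- binarize_outcome(co1$clinical, "os")
  # planted genes should correlate with the median-split label
  cors <- sapply(co1$planted_prognostic_genes, function(g)
    abs(cor(log(co1$expression[g, ]), lab1$label)))
  expect_gt(mean(cors), 0.1)

  co0 <- generate_cohort(400, 30, 5, 0, seed = 21)
  lab0 <- binarize_outcome(co0$clinical, "os")
  cors0 <- sapply(rownames(co0$expression), function(g)
    abs(cor(log(co0$expression[g, ]), lab0$label)))
  # with no effect, no gene should correlate beyond sampling noise
  expect_lt(max(cors0), 4 / sqrt(400))
})

test_that("cohort and protein generators reject bad arguments", {
  expect_error(generate_cohort(0, 10, 2, 1, seed = 1), "n_patients")
  expect_error(generate_cohort(10, 5, 5, 1, seed = 1), "reference")
  expect_error(generate_proteins(5, c(2, 10), seed = 1), "min >= 3")
  expect_error(generate_tissue_panel(0, 5, 10, 2, 1, seed = 1), "n_tumor")
  expect_error(generate_corpus("A", "b", "c", 0, seed = 1), "n_docs")
})

test_that("planted tissue genes dominate the two-sample t statistics", {
  panel <- generate_tissue_panel(10, 10, 50, 5, 3.0, seed = 2)
  tumor <- panel$labels$sample_id[panel$labels$label == "tumor"]
  normal <- panel$labels$sample_id[panel$labels$label == "normal"]
  tstat <- apply(log(panel$expression), 1, function(x)
    abs(t.test(x[tumor], x[normal])$statistic))
  planted_t <- tstat[panel$planted_discriminative_genes]
  other_t <- tstat[setdiff(names(tstat), panel$planted_discriminative_genes)]
  for (pt in planted_t) {
    expect_gte(mean(pt > other_t), 0.9)
  }
})

test_that("protein sequences stay in the amino-acid alphabet with correct lengths", {
  pr <- generate_proteins(50, c(50, 300), seed = 3)
  chars <- unique(strsplit(paste(pr$sequence, collapse = ""), "")[[1]])
  expect_true(all(chars %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  expect_true(all(nchar(pr$sequence) >= 50 & nchar(pr$sequence) <= 300))
  one <- generate_proteins(1, c(3, 3), seed = 0)
  expect_equal(nchar(one$sequence), 3)
  expect_length(unlist(protein_corpus(one)), 1)
})

test_that("untilted 3-mer usage is uniform over the 8000 triplets", {
  pr <- generate_proteins(800, c(150, 250), seed = 5, tilt = 0)
  # offset-0 non-overlapping reading: independent multinomial draws
  toks <- unlist(lapply(pr$sequence, function(s) {
    st <- seq(1, nchar(s) - 2, by = 3)
    substring(s, st, st + 2)
  }))
  counts <- table(toks)
  expect_lte(length(counts), 8000)
  # chi-square against the uniform over all 8000 cells
  observed <- rep(0, 8000)
  observed[seq_along(counts)] <- as.numeric(counts) # cells are exchangeable
  chi <- sum((observed - length(toks) / 8000)^2 / (length(toks) / 8000))
  pval <- pchisq(chi, df = 7999, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("generated SMILES are unique and parse under the tokenizer", {
  cmp <- generate_compounds(200, seed = 5)
  expect_false(any(duplicated(cmp$smiles)))
  sentences <- compound_corpus(cmp)
  expect_length(sentences, 200)
  expect_true(all(lengths(sentences) > 0))
})

test_that("interaction world plants outlier-positive scores and a separable rule", {
  prot <- generate_proteins(20, c(50, 150), seed = 31)
  cmp <- generate_compounds(60, seed = 32)
  world <- generate_interaction_world(prot, cmp, 0.1, seed = 33)
  expect_equal(nrow(world$score_table), 20 * 60)
  expect_true(all(world$score_table$score >= 0 &
                    world$score_table$score <= 1))

  key_all <- paste(world$score_table$protein_id, world$score_table$compound_id)
  key_pos <- paste(world$positive_pairs$protein_id,
                   world$positive_pairs$compound_id)
  expect_true(all(key_pos %in% key_all))
  pos_scores <- world$score_table$score[key_all %in% key_pos]
  expect_gt(median(pos_scores), quantile(world$score_table$score, 0.75))

  # hidden rule separates labels perfectly when evaluated on the latents
  rl <- oncodisco:::world_rule_labels(world)
  expect_gt(min(rl$dot[rl$positive]), max(rl$dot[!rl$positive]))

  # tiny pos_fraction leaves (almost) nothing but bulk scores
  small <- generate_interaction_world(prot, cmp, 1e-9, seed = 33)
  expect_lte(nrow(small$positive_pairs), 1)
})

test_that("sensitivity labels follow the planted logistic rule", {
  cmp <- generate_compounds(40, seed = 41)
  panel <- generate_sensitivity_panel(sprintf("G%03d", 1:50), cmp,
                                      n_lines = 40, seed = 42,
                                      n_driver_genes = 10, gain = 3)
  sens <- panel$sensitivity
  expect_true(all(sens$line_id %in% colnames(panel$lines)))
  expect_true(all(sens$compound_id %in% cmp$id))
  expect_lte(nrow(sens), 40 * 40)

  # recompute the rule directly from the planted pieces
  zs <- scale(t(log(panel$lines)[panel$planted_gene_set, , drop = FALSE]))
  s_line <- rowSums(zs) / sqrt(length(panel$planted_gene_set))
  u_c <- attr(cmp, "latents")[, 1]
  names(s_line) <- colnames(panel$lines)
  eta <- panel$gain * s_line[sens$line_id] * u_c[sens$compound_id]
  p <- plogis(eta)
  # aggregate calibration: total successes within 4 sd of the rule's mean
  expect_lt(abs(sum(sens$success) - sum(p)), 4 * sqrt(sum(p * (1 - p))))
  # and the rule's probabilities separate observed outcomes
  expect_gt(roc_auc_test <- oncodisco:::roc_auc(sens$success, p), 0.7)

  null_panel <- generate_sensitivity_panel(sprintf("G%03d", 1:50), cmp,
                                           n_lines = 40, seed = 42,
                                           n_driver_genes = 0)
  expect_length(null_panel$planted_gene_set, 0)
})

test_that("corpus ground truth is recoverable by exact search", {
  genes <- c("LEF1", "CUL1", "FSHR")
  inhibitors <- c("zotinib", "ABC1234")
  keywords <- c("cancer", "lung cancer")
  corp <- generate_corpus(genes, inhibitors, keywords, 60, seed = 8)
  for (i in seq_len(nrow(corp$tuples))) {
    doc <- corp$corpus$text[corp$corpus$id == corp$tuples$doc_id[i]]
    expect_true(grepl(corp$tuples$gene[i], doc, fixed = TRUE))
    expect_true(grepl(corp$tuples$inhibitor[i], doc, fixed = TRUE))
  }
  # planted gene-keyword co-occurrence is found by the independent oracle
  for (g in genes) {
    for (w in keywords) {
      planted_docs <- unique(corp$gene_keyword$doc_id[
        corp$gene_keyword$gene == g & corp$gene_keyword$keyword == w])
      found <- oracle_cooccurrence(corp$corpus$text, g, w)
      expect_gte(found, length(planted_docs))
    }
  }
})
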