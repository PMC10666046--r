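# Stage 4: score-overlap diagnostics, quartile negative sampling, training
# and screening contracts.

make_scores <- function(vals, compounds = NULL, proteins = NULL) {
  n <- length(vals)
  tibble::tibble(
    compound_id = compounds %||% sprintf("c%02d", seq_len(n)),
    protein_id = proteins %||% sprintf("p%02d", seq_len(n)),
    score = vals)
}

test_that("overlap summary quartiles match direct computation", {
  vals <- c(0.05, 0.1, 0.15, 0.2, 0.25, 0.3, 0.85, 0.9, 0.95, 0.97)
  scores <- make_scores(vals)
  positives <- scores[scores$score > 0.8, c("protein_id", "compound_id")]
  ov <- positive_overlap_summary(scores, positives)
  all_row <- ov$summary[ov$summary$group == "all", ]
  expect_equal(as.numeric(all_row[c("min", "q1", "median", "q3", "max")]),
               as.numeric(quantile(vals, c(0, .25, .5, .75, 1), type = 7)))
  pos_row <- ov$summary[ov$summary$group == "positive", ]
  expect_equal(pos_row$min, 0.85)
  expect_equal(as.numeric(pos_row[c("q1", "median", "q3")]),
               as.numeric(quantile(vals[vals > 0.8], c(.25, .5, .75),
                                   type = 7)))

  # positives = all pairs: both summaries identical, overlap true
  ov_all <- positive_overlap_summary(scores,
                                     scores[, c("protein_id", "compound_id")])
  expect_equal(as.numeric(ov_all$summary[1, c("min", "q1", "median", "q3", "max")]),
               as.numeric(ov_all$summary[2, c("min", "q1", "median", "q3", "max")]))
  expect_true(ov_all$overlap)

  ghost <- tibble::tibble(protein_id = "pXX", compound_id = "cXX")
  expect_warning(positive_overlap_summary(scores,
                                          rbind(positives, ghost)),
                 "absent")
})

test_that("the default synthetic world shows the outlier structure", {
  prot <- generate_proteins(25, c(50, 150), seed = 61)
  cmp <- generate_compounds(80, seed = 62)
  world <- generate_interaction_world(prot, cmp, seed = 63)
  ov <- positive_overlap_summary(world$score_table, world$positive_pairs)
  expect_false(ov$overlap)
  expect_gt(ov$min_positive, ov$upper_whisker)
})

test_that("quartile negative sampling matches the brute-force oracle", {
  # hand case: Q1 of {0.1, 0.2, 0.3, 0.9} is 0.175 -> only 0.1 is negative
  scores <- make_scores(c(0.1, 0.2, 0.3, 0.9))
  positives <- tibble::tibble(protein_id = "p04", compound_id = "c04")
  ds <- assemble_dpi_dataset(positives, scores)
  neg <- ds[ds$label == 0L, ]
  expect_equal(nrow(neg), 1)
  expect_equal(neg$compound_id, "c01")

  set.seed(8)
  for (rep in 1:10) {
    n <- sample(50:400, 1)
    scores <- tibble::tibble(
      compound_id = sprintf("c%03d", sample(40, n, replace = TRUE)),
      protein_id = sprintf("p%03d", sample(40, n, replace = TRUE)),
      score = round(runif(n), 3)) %>%
      dplyr::distinct(.data$compound_id, .data$protein_id, .keep_all = TRUE)
    positives <- scores[sample(nrow(scores), 5), c("protein_id", "compound_id")]
    maxc <- sample(c(5, 20, 1000), 1)
    ds <- assemble_dpi_dataset(positives, scores, max_compounds = maxc)
    neg <- ds[ds$label == 0L, c("protein_id", "compound_id")]
    oracle <- oracle_quartile_negatives(positives, scores, maxc)
    expect_equal(
      sort(paste(neg$protein_id, neg$compound_id)),
      sort(paste(oracle$protein_id, oracle$compound_id)))
    # positives and negatives always disjoint
    expect_length(intersect(paste(neg$protein_id, neg$compound_id),
                            paste(positives$protein_id, positives$compound_id)),
                  0)
  }
})

test_that("a pair listed positive never reappears as negative", {
  scores <- make_scores(c(0.1, 0.1, 0.5, 0.9))
  positives <- tibble::tibble(protein_id = c("p01", "p04"),
                              compound_id = c("c01", "c04"))
  ds <- assemble_dpi_dataset(positives, scores)
  key <- paste(ds$protein_id, ds$compound_id)
  expect_false(any(duplicated(key[ds$label == 1L])))
  expect_equal(sum(ds$label == 1L & ds$protein_id == "p01"), 1)
  expect_false(any(ds$label == 0L & ds$protein_id == "p01" &
                     ds$compound_id == "c01"))
  expect_equal(ds$provenance[ds$label == 1L][1], "positive_list")
  all_pos <- make_scores(c(0.5, 0.5, 0.5, 0.5))
  expect_error(
    assemble_dpi_dataset(all_pos[, c("protein_id", "compound_id")], all_pos),
    "zero negatives")
})

# A small trained world shared by the screening-contract tests.
small_dpi_fixture <- local({
  fixture <- NULL
  function() {
    if (is.null(fixture)) {
      prot <- generate_proteins(12, c(40, 120), seed = 71)
      cmp <- generate_compounds(60, seed = 72)
      world <- generate_interaction_world(prot, cmp, 0.15, seed = 73)
      ptab <- train_token_embedding(protein_corpus(prot), d = 20, seed = 74)
      ctab <- train_token_embedding(compound_corpus(cmp), d = 20, seed = 75,
                                    kind = "substructure_id")
      EP <- oncodisco:::embed_proteins_matrix(prot, ptab)
      EC <- oncodisco:::embed_compounds_matrix(cmp, ctab)
      ds <- assemble_dpi_dataset(world$positive_pairs, world$score_table,
                                 protein_vectors = EP, compound_vectors = EC)
      model <- train_dpi_model(ds, folds = 3, arch = fast_arch(), seed = 76)
      fixture <<- list(prot = prot, cmp = cmp, world = world, ptab = ptab,
                       ctab = ctab, ds = ds, model = model)
    }
    fixture
  }
})

test_that("dpi training consumes concatenated embeddings and reports CV folds", {
  fx <- small_dpi_fixture()
  expect_equal(ncol(attr(fx$ds, "features")), 40) # 2 x d
  expect_length(fx$model$cv$fold_aucs, 3)
  expect_error(train_dpi_model(fx$ds[1:10, ], seed = 1), "no attached")
})

test_that("screening respects thresholds, ordering and monotone nesting", {
  fx <- small_dpi_fixture()
  lib <- generate_compounds(30, seed = 81)
  all_hits <- screen_library(fx$model, fx$prot, lib, fx$ptab, fx$ctab,
                             threshold = 0)
  expect_equal(nrow(all_hits), 12 * 30)
  expect_true(all(diff(all_hits$probability) <= 0))

  h95 <- screen_library(fx$model, fx$prot, lib, fx$ptab, fx$ctab, 0.95)
  h99 <- screen_library(fx$model, fx$prot, lib, fx$ptab, fx$ctab, 0.99)
  key95 <- paste(h95$protein_id, h95$compound_id)
  key99 <- paste(h99$protein_id, h99$compound_id)
  expect_true(all(key99 %in% key95))
  expect_true(all(h95$probability > 0.95))
  h1 <- screen_library(fx$model, fx$prot, lib, fx$ptab, fx$ctab, 1.0)
  expect_true(nrow(h1) == 0 || all(h1$probability > 1 - 1e-12))
})

test_that("hit tallies count per gene and sum to the hit total", {
  hits <- tibble::tibble(
    protein_id = c("GA", "GA", "GA", "GB", "GB"),
    compound_id = sprintf("c%d", 1:5),
    probability = seq(0.99, 0.95, length.out = 5))
  tal <- tally_hits_per_gene(hits)
  expect_equal(tal$gene, c("GA", "GB"))
  expect_equal(tal$n_inhibitors, c(3L, 2L))
  expect_equal(sum(tal$n_inhibitors), nrow(hits))
  empty <- tally_hits_per_gene(hits[0, ])
  expect_equal(nrow(empty), 0)
})
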