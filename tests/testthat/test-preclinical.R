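# Stage 5: cell-line dataset assembly, IC50 model, selectivity filtering.

test_that("cell dataset rows concatenate expression and compound blocks", {
  cmp <- generate_compounds(20, seed = 91)
  panel <- generate_sensitivity_panel(sprintf("G%03d", 1:15), cmp,
                                      n_lines = 12, seed = 92,
                                      n_driver_genes = 4)
  ctab <- train_token_embedding(compound_corpus(cmp), d = 10, seed = 93,
                                kind = "substructure_id")
  EC <- oncodisco:::embed_compounds_matrix(cmp, ctab)
  ds <- assemble_cell_dataset(panel$lines, panel$sensitivity, EC)
  expect_equal(ncol(attr(ds, "features")), 15 + 10)
  expect_equal(nrow(attr(ds, "features")), nrow(ds))
  expect_lte(nrow(ds), 12 * 20)

  # records with unknown lines/compounds are excluded with a warning
  broken <- panel$sensitivity
  broken$line_id[1] <- "NOPE"
  expect_warning(ds2 <- assemble_cell_dataset(panel$lines, broken, EC),
                 "Excluding 1")
  expect_equal(nrow(ds2), nrow(panel$sensitivity) - 1)

  empty <- assemble_cell_dataset(panel$lines, panel$sensitivity[0, ], EC)
  expect_equal(nrow(empty), 0)
})

test_that("IC50 model recovers planted drivers and calibrates on the null panel", {
  cmp <- generate_compounds(60, seed = 29)
  panel <- generate_sensitivity_panel(sprintf("G%03d", 1:40), cmp,
                                      n_lines = 50, seed = 29,
                                      n_driver_genes = 8)
  ctab <- train_token_embedding(compound_corpus(cmp), d = 24, seed = 30,
                                kind = "substructure_id")
  EC <- oncodisco:::embed_compounds_matrix(cmp, ctab)
  ds <- assemble_cell_dataset(panel$lines, panel$sensitivity, EC)
  model <- train_ic50_model(ds, arch = mlp_arch(hidden = 12, maxit = 200),
                            seed = 29)
  expect_gt(model$cv$mean_auc, 0.7)
  expect_lte(nrow(model$gene_ranking), 40) # restricted to the gene block
  top <- model$gene_ranking$gene[seq_len(min(16, nrow(model$gene_ranking)))]
  expect_gte(length(intersect(top, panel$planted_gene_set)), 5)

  null_panel <- generate_sensitivity_panel(sprintf("G%03d", 1:40), cmp,
                                           n_lines = 50, seed = 29,
                                           n_driver_genes = 0)
  ds0 <- assemble_cell_dataset(null_panel$lines, null_panel$sensitivity, EC)
  model0 <- train_ic50_model(ds0, arch = fast_arch(), seed = 29)
  expect_gt(model0$cv$mean_auc, 0.35)
  expect_lt(model0$cv$mean_auc, 0.65)
})

test_that("prediction matrix has probability entries and deterministic rows", {
  cmp <- generate_compounds(30, seed = 95)
  panel <- generate_sensitivity_panel(sprintf("G%03d", 1:12), cmp,
                                      n_lines = 8, seed = 96,
                                      n_driver_genes = 3)
  ctab <- train_token_embedding(compound_corpus(cmp), d = 8, seed = 97,
                                kind = "substructure_id")
  EC <- oncodisco:::embed_compounds_matrix(cmp, ctab)
  ds <- assemble_cell_dataset(panel$lines, panel$sensitivity, EC)
  model <- train_ic50_model(ds, folds = 3, arch = fast_arch(), seed = 98)
  cand <- cmp[1:6, c("id", "smiles")]
  pm <- predict_matrix(model, cand, panel$lines, ctab)
  expect_equal(dim(pm), c(6, 8))
  expect_true(all(pm >= 0 & pm <= 1))
  dup <- cand
  dup$id <- paste0("dup_", dup$id)
  pm2 <- predict_matrix(model, dup, panel$lines, ctab)
  expect_equal(unname(unclass(pm2)), unname(unclass(pm)))
})

test_that("target-line filtering matches a brute-force AND filter", {
  mat <- matrix(c(0.95, 0.99, 0.10,
                  0.91, 0.85, 0.95,
                  0.99, 0.93, 0.97), 3, 3, byrow = TRUE,
                dimnames = list(paste0("m", 1:3), paste0("L", 1:3)))
  class(mat) <- c("prediction_matrix", class(mat))
  expect_equal(filter_by_target_lines(mat, c("L1", "L2"), 0.9),
               c("m1", "m3"))
  expect_equal(filter_by_target_lines(mat, c("L1", "L2"), 0),
               paste0("m", 1:3))
  # monotone: passing set shrinks as the threshold rises
  expect_true(all(filter_by_target_lines(mat, c("L1", "L2"), 0.92) %in%
                    filter_by_target_lines(mat, c("L1", "L2"), 0.9)))
  expect_error(filter_by_target_lines(mat, "L9", 0.9), "Unknown line")
})

test_that("selectivity ranking equals brute-force count-and-sort with tie rules", {
  mat <- matrix(c(0.95, 0.96, 0.97, 0.98, 0.99,
                  0.95, 0.96, 0.10, 0.20, 0.30,
                  0.95, 0.96, 0.10, 0.20, 0.31,
                  0.50, 0.99, 0.99, 0.99, 0.99), 4, 5, byrow = TRUE,
                dimnames = list(paste0("m", 1:4), paste0("L", 1:5)))
  sel <- selectivity_filter(mat, 0.9, c("L1", "L2"), top_n = 4)
  # m4 fails L1; m2 and m3 tie on 2 hit lines -> lower off-target mean wins
  expect_equal(sel$molecule_id, c("m2", "m3", "m1"))
  # the always-active molecule ranks last among passers
  expect_equal(sel$molecule_id[nrow(sel)], "m1")
  expect_equal(
    sel$molecule_id,
    oracle_selectivity(mat, 0.9, c("L1", "L2"), 4))

  set.seed(12)
  for (rep in 1:40) {
    nm <- sample(3:10, 1)
    nl <- sample(3:8, 1)
    m <- matrix(round(runif(nm * nl), 2), nm, nl,
                dimnames = list(sprintf("m%02d", 1:nm),
                                sprintf("L%02d", 1:nl)))
    req <- sample(colnames(m), 2)
    thr <- runif(1, 0.2, 0.8)
    top_n <- sample(1:nm, 1)
    got <- selectivity_filter(m, thr, req, top_n)
    expect_equal(got$molecule_id, oracle_selectivity(m, thr, req, top_n))
    # output always a subset of the AND filter
    expect_true(all(got$molecule_id %in%
                      filter_by_target_lines(m, req, thr)))
  }
})
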