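# Stage 1: normalization, median-split labels, augmentation, Lasso ranking.

test_that("reference-gene normalization matches hand arithmetic and is idempotent", {
  m <- matrix(c(2, 4, 4, 4), 2, 2, byrow = TRUE,
              dimnames = list(c("REF", "T"), c("s1", "s2")))
  norm <- normalize_expression(m, "REF")
  expect_equal(unname(norm["T", ]), c(2, 1))
  expect_equal(unname(norm["REF", ]), c(1, 1))
  expect_equal(unname(normalize_expression(norm, "REF")), unname(norm))

  m_bad <- m
  m_bad["REF", "s2"] <- 0
  expect_error(normalize_expression(m_bad, "REF"), "s2")
  expect_error(normalize_expression(m, "GAPDH"), "not found")
})

test_that("outcome binarization splits at the median with the declared tie rule", {
  cl <- tibble::tibble(patient_id = paste0("p", 1:4),
                       os_time = c(1, 2, 3, 4), pfi_time = c(4, 3, 2, 1))
  lab <- binarize_outcome(cl, "os")
  expect_equal(lab$label, c(0L, 0L, 1L, 1L))
  expect_equal(attr(lab, "median_used"), 2.5)
  expect_equal(nrow(lab), nrow(cl))

  odd <- tibble::tibble(patient_id = paste0("p", 1:3), os_time = c(1, 2, 3))
  expect_equal(binarize_outcome(odd, "os")$label, c(0L, 0L, 1L))
  expect_equal(binarize_outcome(odd, "os", tie_rule = "above")$label,
               c(0L, 1L, 1L))

  flat <- tibble::tibble(patient_id = paste0("p", 1:4), os_time = rep(5, 4))
  expect_error(binarize_outcome(flat, "os"), "identical")
  # pfi endpoint uses the pfi column
  expect_equal(binarize_outcome(cl, "pfi")$label, c(1L, 1L, 0L, 0L))
})

test_that("outcome classifier reports one AUC per fold and enforces stratification", {
  co <- generate_cohort(120, 20, 4, 2.0, seed = 5)
  lab <- binarize_outcome(co$clinical, "os")
  clf <- train_outcome_classifier(co$expression, lab, folds = 5,
                                  arch = fast_arch(), seed = 9)
  expect_length(clf$cv$fold_aucs, 5)
  expect_equal(clf$cv$mean_auc, mean(clf$cv$fold_aucs))
  expect_equal(sort(unique(clf$cv$fold_assignments)), 1:5)
  # every fold contains both classes
  for (f in 1:5) {
    expect_setequal(unique(lab$label[clf$cv$fold_assignments == f]), c(0, 1))
  }
  p <- predict_proba(clf, t(co$expression))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(tidy(clf)$auc, clf$cv$fold_aucs)
  expect_equal(glance(clf)$mean_auc, clf$cv$mean_auc)

  skewed <- lab
  skewed$label <- c(1L, rep(0L, nrow(lab) - 1L))
  expect_error(train_outcome_classifier(co$expression, skewed, folds = 5,
                                        arch = fast_arch(), seed = 9),
               "stratified")
})

test_that("internal AUC agrees with pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(42)
  y <- rbinom(200, 1, 0.4)
  s <- rnorm(200) + y
  expect_equal(
    oncodisco:::roc_auc(y, s),
    as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<"))))
})

test_that("copula augmentation respects counts, ranges and class marginals", {
  co <- generate_cohort(120, 15, 3, 2.0, seed = 31)
  lab <- binarize_outcome(co$clinical, "os")
  tab <- tibble::as_tibble(t(co$expression))
  tab$label <- lab$label

  aug0 <- augment_with_gan(tab, 0, seed = 1)
  expect_equal(nrow(aug0), 120)
  expect_false(any(aug0$.synthetic))

  aug <- augment_with_gan(tab, 500, seed = 1)
  expect_equal(nrow(aug), 620)
  expect_equal(sum(aug$.synthetic), 500)
  feat <- setdiff(names(tab), "label")
  for (j in feat[1:5]) {
    real <- tab[[j]]
    syn <- aug[[j]][aug$.synthetic]
    rng <- range(real)
    pad <- 0.1 * diff(rng)
    expect_true(all(syn >= rng[1] - pad & syn <= rng[2] + pad))
    pooled_se <- sqrt(sd(real)^2 / length(real) + sd(syn)^2 / length(syn))
    expect_lt(abs(mean(syn) - mean(real)), 3 * pooled_se)
  }
  # determinism and backend fallback
  expect_identical(augment_with_gan(tab, 50, seed = 2),
                   augment_with_gan(tab, 50, seed = 2))
  expect_warning(augment_with_gan(tab, 10, seed = 3, backend = "ctgan"),
                 "falling back")
  expect_error(augment_with_gan(tab[1:20, ], 10, seed = 1), "50")
})

test_that("Lasso ranking recovers planted genes and ignores degenerate features", {
  co <- generate_cohort(500, 60, 8, 2.0, seed = 13)
  lab <- binarize_outcome(co$clinical, "os")
  rk <- rank_features_lasso(co$expression, lab, seed = 13)
  expect_true(all(diff(rk$importance) <= 0))
  expect_false(any(duplicated(rk$gene)))
  top15 <- rk$gene[1:15]
  expect_gte(length(intersect(top15, co$planted_prognostic_genes)), 6)

  # constant gene can never be ranked
  expr2 <- co$expression
  expr2["G0002", ] <- 7
  rk2 <- rank_features_lasso(expr2, lab, seed = 13)
  expect_false("G0002" %in% rk2$gene)

  # permuted labels carry no signal
  perm <- lab
  set.seed(99)
  perm$label <- sample(lab$label)
  rk_perm <- suppressWarnings(rank_features_lasso(co$expression, perm,
                                                  seed = 13))
  expect_true(nrow(rk_perm) == 0 ||
                max(rk_perm$importance) < rk$importance[10])
})

test_that("cross-validated AUC is monotone in the planted effect size", {
  aucs <- sapply(c(0, 0.5, 1, 2), function(eff) {
    co <- generate_cohort(300, 60, 8, eff, seed = 77)
    lab <- binarize_outcome(co$clinical, "os")
    train_outcome_classifier(co$expression, lab, arch = fast_arch(),
                             seed = 77)$cv$mean_auc
  })
  expect_true(all(diff(aucs) >= -0.03))
  expect_gt(aucs[4], aucs[1])
})

test_that("Lasso top-20 is stable across cross-validation seeds", {
  co <- generate_cohort(600, 100, 10, 2.0, seed = 55)
  lab <- binarize_outcome(co$clinical, "os")
  top <- lapply(c(1, 2), function(s)
    head(rank_features_lasso(co$expression, lab, seed = s)$gene, 20))
  jaccard <- length(intersect(top[[1]], top[[2]])) /
    length(union(top[[1]], top[[2]]))
  expect_gte(jaccard, 0.5)
})

test_that("endpoint rankings merge by best rank with declared tie-breaks", {
  os <- tibble::tibble(gene = c("A", "B", "C"), importance = c(3, 2, 1),
                       rank = 1:3)
  pfi <- tibble::tibble(gene = c("C", "D"), importance = c(5, 4), rank = 1:2)
  merged <- merge_gene_lists(os, pfi, top_k = 3)
  expect_equal(nrow(merged), 4)
  # best ranks: C -> 1 (imp 1+5=6), A -> 1 (imp 3); C precedes A on importance
  expect_equal(merged$gene, c("C", "A", "D", "B"))

  same <- merge_gene_lists(os, os, top_k = 3)
  expect_equal(same$gene, os$gene)

  disjoint <- merge_gene_lists(
    os, tibble::tibble(gene = c("X", "Y", "Z"), importance = c(9, 8, 7),
                       rank = 1:3), top_k = 3)
  expect_equal(nrow(disjoint), 6)
})
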