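test_that("rank AUC counts won positive-negative comparisons", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_rank(c(0.9, 0.8, 0.2, 0.1), c(0, 1, 0, 1)), 0.25)
  expect_equal(auc_rank(rep(1, 6), c(1, 1, 1, 0, 0, 0)), 0.5)  # ties
  # invariance under strictly monotone transforms
  set.seed(14)
  s <- rnorm(50); l <- rbinom(50, 1, 0.4)
  expect_equal(auc_rank(s, l), auc_rank(exp(s), l))
  expect_equal(auc_rank(s, l), auc_rank(rank(s), l))
  expect_error(auc_rank(s, rep(1, 50)), "both classes")
})

test_that("categorical entropy follows the closed forms and bounds", {
  expect_equal(categorical_entropy(c(0.5, 0.5)), 1)
  expect_equal(categorical_entropy(c(1, 0)), 0)
  expect_equal(categorical_entropy(c(0.25, 0.75)), 0.811278,
               tolerance = 1e-6)
  set.seed(2)
  for (i in 1:10) {
    k <- sample(2:6, 1)
    p <- runif(k); p <- p / sum(p)
    h <- categorical_entropy(p)
    expect_gte(h, 0)
    expect_lte(h, log2(k) + 1e-12)
  }
  expect_error(categorical_entropy(c(0.5, 0.4)), "sum to 1")
  expect_error(categorical_entropy(c(1.2, -0.2)), "non-negative")
})

test_that("fold-change entropy uses sqrt-count equal-width binning", {
  expect_equal(module_fold_change_entropy(rep(1.3, 5)), 0)
  expect_equal(module_fold_change_entropy(c(-2, 2)), 1)  # two bins
  # manual 8-gene oracle: 3 bins over [0, 6], width 2
  lfc <- c(0.1, 0.5, 1.9, 2.1, 3.0, 4.1, 5.0, 6.0)
  counts <- c(3, 2, 3)   # [0,2], (2,4], (4,6]
  expect_equal(module_fold_change_entropy(lfc),
               -sum(counts / 8 * log2(counts / 8)), tolerance = 1e-12)
  expect_error(module_fold_change_entropy(numeric(0)), "empty")
})

test_that("dysregulation entropies cover the boundary cases", {
  none <- module_dysregulation_entropies(rep(FALSE, 4), rep("none", 4))
  expect_equal(unname(none), c(0, 0))
  all_up <- module_dysregulation_entropies(rep(TRUE, 4), rep("up", 4))
  expect_equal(unname(all_up), c(0, 0))
  half <- module_dysregulation_entropies(c(TRUE, TRUE, FALSE, FALSE),
                                         c("up", "up", "none", "none"))
  expect_equal(unname(half), c(1, 1))
  expect_error(
    module_dysregulation_entropies(c(TRUE, FALSE), c("none", "none")),
    "de_flag")
})

test_that("DE annotation derives flags from the printed thresholds", {
  tbl <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    log_fold_change = c(2, -3, 0.5, 2),
                    fdr = c(0.01, 0.04, 0.01, 0.2))
  ann <- derive_de_annotation(tbl)
  expect_identical(ann$de_flag, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(ann$de_direction, c("up", "down", "none", "none"))
})

test_that("average shared validated microRNAs enumerates pairs", {
  map <- target_map(c("g1", "g1", "g2", "g2", "g3"),
                    c("a", "b", "b", "c", "c"))
  expect_equal(avg_shared_validated_mirnas(c("g1", "g2", "g3"), map),
               2 / 3, tolerance = 1e-12)
  same <- target_map(c("g1", "g2", "g3"), rep("a", 3))
  expect_equal(avg_shared_validated_mirnas(c("g1", "g2", "g3"), same), 1)
  # genes without validated targets share nothing
  expect_equal(avg_shared_validated_mirnas(c("gX", "gY"), map), 0)
  expect_true(is.na(avg_shared_validated_mirnas("g1", map)))
})

test_that("one-sided metric comparisons detect stochastic ordering", {
  set.seed(7)
  a <- rnorm(200, mean = -0.5)
  b <- rnorm(200)
  expect_lt(compare_module_metrics(a, b, "ks", alternative = "less"), 0.01)
  expect_lt(compare_module_metrics(a, b, "wilcoxon", alternative = "less"),
            0.01)
  expect_gt(compare_module_metrics(b, a, "ks", alternative = "less"), 0.5)
  x <- rnorm(50)
  expect_gt(compare_module_metrics(x, x, "ks", alternative = "less"), 0.99)
  expect_error(compare_module_metrics(numeric(0), x, "ks",
                                      alternative = "less"), "empty")
  expect_error(compare_module_metrics(x, x, "ks"))   # direction required
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(15)
  p <- runif(30)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p - 1e-15))
  expect_identical(order(adj[order(p)]),
                   seq_along(p))  # monotone in the ordered p-values
})

test_that("CNV filter flags genes off-diploid in >5% of samples", {
  cnv <- rbind(all2 = rep(2L, 20),
               one3 = c(rep(2L, 19), 3L),       # 5% exactly -> not flagged
               many = c(rep(2L, 16), 1L, 3L, 4L, 0L))
  colnames(cnv) <- sprintf("s%02d", 1:20)
  expect_identical(cnv_gene_filter(cnv), "many")
  small <- rbind(g = c(2L, 2L, 2L, 2L, 3L))    # 0.2 > 0.05
  colnames(small) <- paste0("s", 1:5)
  expect_identical(cnv_gene_filter(small), "g")
})

test_that("methylation filter needs >1 DMS and a dominant direction", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                      start = c(10000, 50000, 90000, 130000))
  sites <- data.frame(
    position = c(10100,                       # g1: single DMS
                 49000, 50100, 51000, 51900,  # g2: 3 up, 1 down
                 89500, 90500, 91000, 91500,  # g3: 4 up
                 130100, 130200),             # g4: fails FDR
    fdr = c(rep(0.01, 9), 0.5, 0.5),
    mean_diff = c(0.5,
                  0.5, 0.5, 0.5, -0.5,
                  0.4, 0.4, 0.3, 0.3,
                  0.5, 0.5))
  expect_identical(dms_gene_filter(sites, genes), "g3")
  # 3/4 same direction is not strictly greater than 0.75
  expect_false("g2" %in% dms_gene_filter(sites, genes))
})

test_that("module enrichment reuses the hypergeometric tail", {
  uni <- paste0("g", 1:10)
  expect_equal(module_enrichment(uni[1:3], uni[c(1, 2, 5, 6)], uni),
               1 / 3, tolerance = 1e-12)
  expect_equal(module_enrichment(uni[1:3], uni, uni), 1)  # certain event
  expect_equal(module_enrichment(uni[1:3], character(0), uni), 1)
  expect_error(module_enrichment(c("g1", "zz"), uni[1], uni), "universe")
})
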