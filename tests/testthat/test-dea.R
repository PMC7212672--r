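test_that("rank-sum p matches exact enumeration and wilcox.test on small groups", {
  # frozen example: fully separated triplets, p = 2 * 1/C(6,3) = 0.1
  Y <- matrix(c(1, 2, 3, 4, 5, 6), 1)
  dea <- wilcoxon_dea(Y, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(dea$p, 0.1, tolerance = 1e-12)
  # all tie-free group sizes up to 6 against R's exact Wilcoxon
  set.seed(41)
  for (n1 in 2:6) for (n2 in 2:6) {
    x <- rnorm(n1); y <- rnorm(n2)
    ours <- wilcoxon_dea(matrix(c(x, y), 1),
                         c(rep(TRUE, n1), rep(FALSE, n2)))$p
    ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-10)
  }
  # tied data against enumeration written independently in the helper
  set.seed(42)
  for (rep in 1:10) {
    x <- sample(0:2, 5, replace = TRUE)
    y <- sample(0:2, 6, replace = TRUE)
    ours <- wilcoxon_dea(matrix(c(x, y), 1),
                         c(rep(TRUE, 5), rep(FALSE, 6)))$p
    expect_equal(ours, enum_mw_p(x, y), tolerance = 1e-10)
  }
})

test_that("identical groups give p = 1 and zero logFC; labels antisymmetric", {
  Y <- matrix(rep(c(1, 2, 3), 2), 1)
  mask <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  dea <- wilcoxon_dea(Y, mask)
  expect_equal(dea$p, 1)
  expect_equal(dea$logFC, 0)
  # swapping labels negates logFC and leaves p unchanged
  set.seed(7)
  Y2 <- matrix(rnorm(40, 2), 2)
  mask2 <- rep(c(TRUE, FALSE), 10)
  a <- wilcoxon_dea(Y2, mask2)
  b <- wilcoxon_dea(Y2, !mask2)
  expect_equal(a$logFC, -b$logFC, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("constant genes yield p = 1, adjusted p dominates raw p", {
  Y <- rbind(rep(5, 10), rnorm(10))
  dea <- wilcoxon_dea(Y, rep(c(TRUE, FALSE), 5))
  expect_equal(dea$p[1], 1)
  expect_true(all(dea$p_adj >= dea$p))
  expect_identical(dea$direction, ifelse(dea$logFC > 0, "up",
                                         ifelse(dea$logFC < 0, "down", "none")))
  expect_error(wilcoxon_dea(Y, rep(TRUE, 10)), "non-empty")
})

test_that("signature filters apply the logFC, adjusted-p, and expression rules", {
  dea <- data.frame(
    gene = c("a", "b", "c", "d"),
    mean_biased = c(1, 1, 1, 0.1),
    mean_unbiased = c(0.5, 0.5, 0.5, 0.05),
    logFC = c(0.30, 0.20, -0.40, 0.50),
    p = c(1e-5, 1e-5, 1e-6, 0.5),
    p_adj = c(5e-4, 5e-4, 5e-4, 0.9),
    direction = c("up", "up", "down", "up"))
  sig <- define_signature(dea, min_abs_logfc = 0.25, max_adj_p = 0.001)
  expect_setequal(sig$gene, c("a", "c"))   # b fails |logFC|, d fails p_adj
  expect_identical(sig$direction[sig$gene == "a"], "up")
  # expression floor applies to the larger group mean
  sig2 <- define_signature(dea, min_abs_logfc = 0.25, max_adj_p = 0.001,
                           min_expr = 0.5)
  expect_setequal(sig2$gene, c("a", "c"))
  sig3 <- define_signature(dea[0, , drop = FALSE])
  expect_equal(nrow(sig3), 0)
})

test_that("planted effects are recovered with controlled false discoveries", {
  cfg <- sim_config(n_genes = 1000, n_cells_per_condition = 300,
                    conditions = c(0, 24), downreg_fraction = 0.3,
                    downreg_rate = 0.05, n_cell_types = 2, seed = 13)
  sim <- simulate_counts(cfg)
  kept <- filter_genes(sim$matrix, 5)
  norm <- size_factor_normalize(kept)
  dea <- wilcoxon_dea(norm, kept$cell_data$affected)
  truth <- sim$truth$gene[match(dea$gene, sim$truth$gene$gene), ]
  called <- dea$p_adj < 0.001
  expect_gt(sum(called), 50)
  fdr <- mean(truth$direction[called] == "null")
  expect_lte(fdr, 0.05)
})

test_that("hypergeometric enrichment matches binomial-coefficient arithmetic", {
  # universe 20, term 5, target 6, overlap 4:
  # p = [C(5,4) C(15,2) + C(5,5) C(15,1)] / C(20,6)
  universe <- paste0("g", 1:20)
  term <- universe[1:5]
  target <- universe[c(1:4, 6, 7)]
  oracle <- (choose(5, 4) * choose(15, 2) + choose(5, 5) * choose(15, 1)) /
    choose(20, 6)
  res <- set_enrichment(target, universe, list(T1 = term),
                        max_p = 1, min_or = 0)
  expect_equal(res$p, oracle, tolerance = 1e-12)
  expect_equal(res$overlap, 4)
})

test_that("enrichment size and odds-ratio filters drop terms", {
  universe <- paste0("g", 1:1000)
  sets <- list(
    too_general = universe[1:600],   # size >= 600 excluded before testing
    too_specific = universe[1:2],    # size < 3 excluded
    ok = universe[1:20])
  target <- universe[1:10]
  res <- set_enrichment(target, universe, sets, max_p = 1, min_or = 0)
  expect_identical(res$term, "ok")
  # strong p but weak odds ratio is filtered under the default min_or = 2
  res2 <- set_enrichment(target, universe, sets, max_p = 1, min_or = 1e6)
  expect_equal(nrow(res2), 0)
  expect_error(set_enrichment(c("zzz"), universe, sets), "zzz")
})

test_that("signature overlap computes Jaccard and honors top-n truncation", {
  expect_equal(signature_overlap(c("A", "B"), c("A", "B"))$jaccard, 1)
  expect_equal(signature_overlap(c("A", "B"), c("C", "D"))$jaccard, 0)
  ov <- signature_overlap(c("A", "B", "C", "D"), c("C", "D", "E"))
  expect_equal(ov$jaccard, 0.4)
  expect_setequal(ov$intersection, c("C", "D"))
  # ranked truncation keeps the largest |ranking| entries
  a <- stats::setNames(c(3, -2, 1, 0.5), c("A", "B", "C", "D"))
  b <- stats::setNames(c(5, 4, 0.1), c("B", "E", "C"))
  ov2 <- signature_overlap(a, b, top_n = 2)
  expect_identical(ov2$intersection, "B")
  expect_error(signature_overlap(c("A"), c("A"), top_n = 1), "ranking")
})
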