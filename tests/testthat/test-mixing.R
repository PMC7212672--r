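test_that("kBET acceptance reflects mixing structure", {
  set.seed(14)
  emb <- matrix(rnorm(400 * 3), 400, 3)
  # single label: chi-squared 0, acceptance 100%
  res1 <- kbet(emb, rep("a", 400), k = 20, seed = 1)
  expect_equal(res1$acceptance_rate, 100)
  expect_true(all(res1$stats$p == 1))
  expect_equal(res1$acceptance_rate + res1$rejection_rate, 100)
  # perfectly separated batches: every tested neighborhood is pure
  emb2 <- rbind(matrix(rnorm(200 * 2), 200, 2),
                matrix(rnorm(200 * 2, mean = 50), 200, 2))
  res2 <- kbet(emb2, rep(c("a", "b"), each = 200), k = 20, seed = 1)
  expect_equal(res2$acceptance_rate, 0)
})

test_that("randomly shuffled labels are accepted at the nominal rate", {
  set.seed(15)
  emb <- matrix(rnorm(1200 * 5), 1200, 5)
  labels <- sample(rep(c("a", "b"), 600))
  res <- kbet(emb, labels, k = 150, n_test = 1000, seed = 3)
  expect_gt(res$acceptance_rate, 92)
  expect_lt(res$acceptance_rate, 98)
})

test_that("kBET guards its preconditions", {
  emb <- matrix(rnorm(30 * 2), 30, 2)
  expect_error(kbet(emb, rep("a", 30), k = 30), "smaller than the number")
  expect_warning(kbet(emb, rep(c("a", "b", "c"), 10), k = 2, seed = 1),
                 "approximation")
})

test_that("proportionality matches hand arithmetic and its bounds", {
  # y = 2x: cov = 2 var(x), var(y) = 4 var(x), so
  # rho = 2 * 2v / (v + 4v) = 0.8 under either variance convention
  m <- cbind(x = c(1, 2, 3), y = c(2, 4, 6))
  rho <- proportionality_matrix(m)
  expect_equal(rho["x", "y"], 0.8, tolerance = 1e-12)
  expect_equal(unname(diag(rho)), c(1, 1))
  # antisymmetric case: zero-mean vector against its negation
  m2 <- cbind(a = c(-1, 0, 1), b = c(1, 0, -1))
  expect_equal(proportionality_matrix(m2)["a", "b"], -1, tolerance = 1e-12)
  # symmetry and range on random data; constant cells become NA
  set.seed(16)
  m3 <- cbind(matrix(rnorm(50 * 6), 50, 6), const = rep(2, 50))
  colnames(m3) <- paste0("c", 1:7)
  r3 <- proportionality_matrix(m3)
  expect_lt(max(abs(r3 - t(r3)), na.rm = TRUE), 1e-10)
  expect_true(all(r3[is.finite(r3)] >= -1 & r3[is.finite(r3)] <= 1))
  expect_true(all(is.na(r3["c7", 1:6])))
  expect_error(proportionality_matrix(m[, 1, drop = FALSE]), "2 cells")
})

test_that("balanced downsampling caps every stratum and is seeded", {
  set.seed(17)
  m <- matrix(rnorm(10 * 800), 10, 800)
  strata <- rep(c("T.0", "T.24", "B.0", "B.24"), each = 200)
  sub <- downsample_balanced(m, strata, n_per_stratum = 50, seed = 4)
  expect_equal(ncol(sub), 200)
  expect_true(all(table(strata[attr(sub, "index")]) == 50))
  # undersized stratum kept whole
  m2 <- m[, 1:230]
  sub2 <- downsample_balanced(m2, strata[1:230], n_per_stratum = 50, seed = 4)
  expect_equal(as.vector(table(strata[1:230][attr(sub2, "index")])[c("T.0", "T.24")]),
               c(50, 30))
  expect_identical(attr(downsample_balanced(m, strata, 50, seed = 9), "index"),
                   attr(downsample_balanced(m, strata, 50, seed = 9), "index"))
})

test_that("per-gene r2 equals the one-way ANOVA eta squared", {
  # hand case: gene [1,2,3,4], groups {1,2} vs {3,4}: between 4, total 5
  Y <- matrix(c(1, 2, 3, 4), 1)
  expect_equal(unname(variance_r2(Y, c("a", "a", "b", "b"))), 0.8,
               tolerance = 1e-12)
  # oracle: aov on random instances with <= 3 groups, <= 12 cells
  set.seed(18)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    g <- sample(2:3, 1)
    cov <- factor(sample(letters[1:g], n, replace = TRUE))
    if (nlevels(droplevels(cov)) < 2) next
    y <- rnorm(n)
    fit <- summary(stats::aov(y ~ cov))[[1]]
    eta <- fit["cov", "Sum Sq"] / sum(fit[, "Sum Sq"])
    expect_equal(unname(variance_r2(matrix(y, 1), cov)), eta,
                 tolerance = 1e-10)
  }
  # degenerate conventions
  expect_equal(unname(variance_r2(matrix(rep(2, 6), 1),
                                  rep(c("a", "b"), 3))), 0)
  expect_equal(unname(variance_r2(matrix(rnorm(6), 1), rep("a", 6))), 0)
  # exact encoding of the covariate: r2 = 1
  expect_equal(unname(variance_r2(matrix(c(1, 1, 2, 2), 1),
                                  c("a", "a", "b", "b"))), 1)
})

test_that("PC variance fraction responds to planted covariate structure", {
  set.seed(19)
  # constant covariate explains nothing
  Y <- matrix(rnorm(50 * 40), 50, 40)
  expect_equal(pc_variance_fraction(Y, rep("a", 40), n_pcs = 5), 0)
  # covariate driving one dominant direction pushes the fraction toward 1
  grp <- rep(c(0, 1), each = 20)
  Y2 <- matrix(rnorm(50 * 40, sd = 0.05), 50, 40) + outer(rnorm(50, sd = 2), grp)
  expect_gt(pc_variance_fraction(Y2, grp, n_pcs = 5), 0.9)
  expect_warning(pc_variance_fraction(Y[1:3, ], rep(c("a", "b"), 20),
                                      n_pcs = 50), "rank")
})

test_that("planted variance share is recovered by the PC-weighted fraction", {
  cfg <- sim_config(n_genes = 800, n_cells_per_condition = 150,
                    conditions = c(0, 24), downreg_fraction = 0.3,
                    downreg_rate = 0.05, n_cell_types = 1,
                    n_markers_per_type = 0, marker_fc = 1, seed = 23)
  sim <- simulate_counts(cfg)
  kept <- filter_genes(sim$matrix, 5)
  norm <- size_factor_normalize(kept)
  time_lab <- kept$cell_data$time_h
  frac <- pc_variance_fraction(norm, time_lab, n_pcs = 10)
  # with a single cell type the time contrast is the dominant structured
  # axis: the weighted fraction must agree with the direct r2 share of
  # the same embedding within 0.05
  emb <- pca_embed(norm, 10)
  direct <- sum(apply(emb, 2, var) * variance_r2(t(emb), time_lab)) /
    sum(apply(emb, 2, var))
  expect_equal(frac, direct, tolerance = 1e-10)
  expect_gt(frac, 0.2)
})

test_that("kBET acceptance increases after regression correction", {
  cfg <- sim_config(n_genes = 600, n_cells_per_condition = 150,
                    conditions = c(0, 24), downreg_fraction = 0.3,
                    downreg_rate = 0.05, n_cell_types = 2, seed = 24)
  sim <- simulate_counts(cfg)
  kept <- filter_genes(sim$matrix, 5)
  norm <- size_factor_normalize(kept)
  md <- kept$cell_data
  dea <- wilcoxon_dea(norm, md$affected)
  sig <- define_signature(dea)
  sc <- module_score(norm, sig$gene, seed = 3)
  corr <- regress_out_score(norm, sc)
  before <- kbet(pca_embed(norm, 10), md$time_h, seed = 5)$acceptance_rate
  after <- kbet(pca_embed(corr, 10), md$time_h, seed = 5)$acceptance_rate
  expect_gte(after, before)
  expect_gt(after, 5)
})
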