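test_that("degenerate control sampling reduces to a mean difference", {
  # 6 genes, one bin, controls = all 3 non-signature genes: the score is
  # mean(signature rows) - mean(other rows), hand-computable per cell
  Y <- matrix(c(1, 2, 3, 4, 5, 6,
                2, 2, 2, 2, 2, 2), 6, 2)
  rownames(Y) <- paste0("g", 1:6)
  colnames(Y) <- c("c1", "c2")
  sig <- c("g1", "g2", "g3")
  sc <- module_score(Y, sig, n_bins = 1, n_ctrl = 3, seed = 1)
  expected <- colMeans(Y[1:3, ]) - colMeans(Y[4:6, ])
  expect_equal(as.numeric(sc), unname(expected), tolerance = 1e-12)
})

test_that("module score is shift-invariant and seed-reproducible", {
  set.seed(5)
  Y <- matrix(rnorm(100 * 30, 2), 100, 30,
              dimnames = list(paste0("g", 1:100), paste0("c", 1:30)))
  sig <- paste0("g", 1:10)
  a <- module_score(Y, sig, seed = 3)
  b <- module_score(Y + 7, sig, seed = 3)
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-10)
  expect_identical(as.numeric(a), as.numeric(module_score(Y, sig, seed = 3)))
  expect_false(identical(as.numeric(a),
                         as.numeric(module_score(Y, sig, seed = 4))))
})

test_that("null signatures score near zero; absent genes warned or rejected", {
  set.seed(6)
  Y <- matrix(rnorm(200 * 50), 200, 50,
              dimnames = list(paste0("g", 1:200), paste0("c", 1:50)))
  sc <- module_score(Y, paste0("g", sample(200, 20)), seed = 2)
  expect_lt(abs(mean(sc)), 0.1)
  expect_warning(module_score(Y, c("g1", "g2", "absent"), seed = 1),
                 "absent")
  expect_error(module_score(Y, c("nope"), seed = 1), "no signature gene")
})

test_that("AUC equals concordant-pair counting on all small inputs", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    x <- sample(1:5, n, replace = TRUE)   # ties included
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    expect_equal(timedrift:::auc_rank(x, labels), pair_auc(x, labels),
                 tolerance = 1e-12)
  }
  # independent package cross-check on one larger case
  skip_if_not_installed("pROC")
  x <- rnorm(100); labels <- rbinom(100, 1, 0.5) == 1
  ref <- as.numeric(pROC::auc(pROC::roc(labels, x, quiet = TRUE,
                                        direction = "<")))
  expect_equal(timedrift:::auc_rank(x, labels), ref, tolerance = 1e-10)
})

test_that("classifier training AUC matches pair enumeration", {
  m <- fit_classifier(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(m$auc_train, 0.75)   # 3 of 4 pos-neg pairs concordant
  # perfect separation: AUC 1, capped coefficients, warning
  expect_warning(
    ms <- fit_classifier(c(rep(0, 8), rep(5, 8)),
                         c(rep(0, 8), rep(1, 8))),
    "separation")
  expect_equal(ms$auc_train, 1)
  expect_true(is.finite(ms$slope))
  expect_error(fit_classifier(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("null scores give chance-level AUC", {
  set.seed(8)
  sc <- rnorm(2000)
  labels <- rbinom(2000, 1, 0.5) == 1
  m <- suppressWarnings(fit_classifier(sc, labels))
  expect_lt(abs(m$auc_train - 0.5), 0.03)
})

test_that("predicted AUC is invariant to monotone score transforms", {
  set.seed(9)
  sc <- rnorm(200)
  labels <- rbinom(200, 1, plogis(2 * sc)) == 1
  m <- fit_classifier(sc, labels)
  a1 <- predict_auc(m, sc, labels)
  a2 <- predict_auc(m, exp(sc), labels)   # monotone transform of scores
  expect_equal(a1$auc, timedrift:::auc_rank(sc, labels), tolerance = 1e-12)
  expect_equal(a2$auc, timedrift:::auc_rank(exp(sc), labels),
               tolerance = 1e-12)
  # ROC endpoints
  expect_equal(a1$roc$fpr[1], 0); expect_equal(a1$roc$tpr[1], 0)
  expect_equal(a1$roc$fpr[nrow(a1$roc)], 1)
  expect_equal(a1$roc$tpr[nrow(a1$roc)], 1)
})

test_that("regression correction honors its algebraic contracts", {
  set.seed(10)
  n <- 40
  sc <- rnorm(n)
  scc <- sc - mean(sc)
  Y <- rbind(
    perfect = 2 * sc,                         # exact fit: residuals zero
    ortho = {v <- rnorm(n); v - scc * sum(v * scc) / sum(scc^2)},
    noisy = rnorm(n))
  colnames(Y) <- paste0("c", 1:n)
  out <- regress_out_score(Y, sc)
  expect_true(all(out["perfect", ] == 0))
  # slope-zero gene: corrected equals the z-scored original
  z <- (Y["ortho", ] - mean(Y["ortho", ])) / sd(Y["ortho", ])
  expect_equal(out["ortho", ], z, tolerance = 1e-10)
  # OLS orthogonality for every gene
  r <- suppressWarnings(cor(t(out), sc))
  expect_true(all(abs(r[is.finite(r)]) < 1e-8))
  # per-cell-type grouping: orthogonality holds within each group
  types <- rep(c("A", "B"), each = n / 2)
  out2 <- regress_out_score(Y, sc, types)
  for (g in c("A", "B")) {
    ix <- types == g
    r2 <- suppressWarnings(cor(t(out2[, ix]), sc[ix]))
    expect_true(all(abs(r2[is.finite(r2)]) < 1e-8))
  }
  expect_error(regress_out_score(Y, sc, c("A", rep("B", n - 1))),
               "fewer than 3")
})

test_that("bootstrap grid emits one row per percentage and replicate", {
  set.seed(12)
  Y <- matrix(rnorm(100 * 120), 100, 120,
              dimnames = list(paste0("g", 1:100), paste0("c", 1:120)))
  aff <- rep(c(TRUE, FALSE), 60)
  sc <- rnorm(120)
  bt <- bootstrap_silhouette(Y, aff, sc, pct_grid = c(30, 50), n_cells = 40,
                             reps = 3, n_pcs = 5, seed = 2)
  expect_equal(nrow(bt), 6)
  expect_equal(unique(bt$pct), c(30, 50))
  # random labels on structureless data: silhouettes near zero
  expect_lt(max(abs(bt$silhouette_before)), 0.2)
  expect_error(bootstrap_silhouette(Y, aff, sc, pct_grid = 0, n_cells = 40,
                                    reps = 1, seed = 1), "empty")
})
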