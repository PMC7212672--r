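#' k-nearest-neighbor batch-effect test (kBET-style acceptance rate)
#'
#' For each tested cell, the batch-label composition of its `k` nearest
#' Euclidean neighbors (the cell itself included) is compared with the
#' global label distribution by a Pearson chi-squared test with
#' `(levels - 1)` degrees of freedom (asymptotic p, no continuity
#' correction). The acceptance rate is the percentage of tested cells with
#' p > 0.05: high acceptance means the batches are locally well mixed.
#'
#' @param embedding cells x d coordinate matrix (e.g. [pca_embed()]).
#' @param batch_labels per-cell labels; unused factor levels are dropped.
#' @param k neighborhood size; default `max(10, floor(0.25 * n / L))`, a
#'   quarter of the mean batch size. A warning is issued when `k` is below
#'   the number of labels (poor chi-squared approximation).
#' @param n_test number of cells tested (seeded sample without
#'   replacement); default `min(n, 1000)`.
#' @param seed integer seed for the test-cell sample.
#' @return `KbetResult` list: `stats` (per tested cell: index, chi2, p),
#'   `acceptance_rate`, `rejection_rate` (percent, summing to 100), `k`,
#'   `n_tested`.
#' @export
kbet <- function(embedding, batch_labels, k = NULL, n_test = NULL,
                 seed = 1L) {
  E <- as.matrix(embedding)
  n <- nrow(E)
  f <- droplevels(factor(batch_labels))
  if (length(f) != n) stop("batch_labels must align to the embedding rows")
  L <- nlevels(f)
  if (is.null(k)) k <- max(10L, floor(0.25 * n / max(L, 1)))
  k <- min(as.integer(k), n)
  if (k < 1) stop("k must be positive")
  if (k >= n) stop("k must be smaller than the number of cells")
  if (L >= 2 && k < L)
    warning("k is smaller than the number of batch labels; ",
            "the chi-squared approximation will be poor")
  if (is.null(n_test)) n_test <- min(n, 1000L)
  set.seed(as.integer(seed))
  test_idx <- sample.int(n, min(n_test, n))

  if (L < 2) {
    stats_df <- data.frame(cell = test_idx, chi2 = 0, p = 1)
  } else {
    freq <- as.numeric(table(f)) / n
    expd <- k * freq
    sq <- rowSums(E^2)
    ## squared Euclidean distances from test cells to all cells
    D2 <- outer(sq[test_idx], sq, "+") - 2 * E[test_idx, , drop = FALSE] %*% t(E)
    chi2 <- numeric(length(test_idx))
    for (i in seq_along(test_idx)) {
      nb <- order(D2[i, ])[seq_len(k)]
      obs <- tabulate(f[nb], nbins = L)
      chi2[i] <- sum((obs - expd)^2 / expd)
    }
    stats_df <- data.frame(cell = test_idx, chi2 = chi2,
                           p = stats::pchisq(chi2, df = L - 1,
                                             lower.tail = FALSE))
  }
  acc <- 100 * mean(stats_df$p > 0.05)
  structure(list(stats = stats_df, acceptance_rate = acc,
                 rejection_rate = 100 - acc, k = k,
                 n_tested = nrow(stats_df)),
            class = "KbetResult")
}

#' @method print KbetResult
#' @export
print.KbetResult <- function(x, ...) {
  cat(sprintf("KbetResult: acceptance %.1f%% (k = %d, %d cells tested)\n",
              x$acceptance_rate, x$k, x$n_tested))
  invisible(x)
}

#' Pairwise proportionality similarity between cells
#'
#' For two cells' log-scale expression vectors x and y,
#' `rho_p = 2 cov(x, y) / (var(x) + var(y))` with the population (1/n)
#' convention. Bounded in `[-1, 1]`, 1 on the diagonal; cells with a
#' constant expression vector have undefined similarity and are reported
#' as `NA`.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param cells_subset optional column index selecting the cells.
#' @param order_by optional data.frame (rows = selected cells, e.g. cell
#'   type and time) used to sort the matrix for display; recorded in
#'   `attr(, "ordering")`.
#' @return symmetric cells x cells matrix of class `SimilarityMatrix`.
#' @export
proportionality_matrix <- function(norm, cells_subset = NULL,
                                   order_by = NULL) {
  X <- as.matrix(norm)
  if (!is.null(cells_subset)) X <- X[, cells_subset, drop = FALSE]
  if (ncol(X) < 2) stop("at least 2 cells are required")
  if (!is.null(order_by)) {
    ord <- do.call(order, as.list(order_by))
    X <- X[, ord, drop = FALSE]
    order_by <- order_by[ord, , drop = FALSE]
  }
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / n
  v <- diag(C)
  rho <- 2 * C / outer(v, v, "+")
  rho[v == 0, ] <- NA_real_
  rho[, v == 0] <- NA_real_
  rho <- (rho + t(rho)) / 2          # exact symmetry against rounding
  d <- diag(rho); d[v > 0] <- 1; diag(rho) <- d
  attr(rho, "ordering") <- order_by
  class(rho) <- c("SimilarityMatrix", "matrix", "array")
  rho
}

#' Balanced downsampling across strata
#'
#' Samples up to `n_per_stratum` cells per stratum without replacement
#' (all cells when a stratum is smaller), so that e.g. cell types and time
#' points are equally represented before similarity analysis.
#'
#' @param m genes x cells matrix or [count_matrix()].
#' @param strata_labels per-cell stratum labels (e.g.
#'   `interaction(cell_type, time)`).
#' @param n_per_stratum target cells per stratum (default 50).
#' @param seed integer seed.
#' @return the subsetted object, with the chosen column indices in
#'   `attr(, "index")`.
#' @export
downsample_balanced <- function(m, strata_labels, n_per_stratum = 50,
                                seed = 1L) {
  n <- if (inherits(m, "CountMatrix")) ncol(m$counts) else ncol(m)
  if (length(strata_labels) != n)
    stop("strata_labels must align to the cells")
  set.seed(as.integer(seed))
  idx <- sort(unlist(lapply(split(seq_len(n), strata_labels), function(ix) {
    if (length(ix) <= n_per_stratum) ix else sample(ix, n_per_stratum)
  }), use.names = FALSE))
  out <- if (inherits(m, "CountMatrix")) subset_cells(m, cells = idx)
         else m[, idx, drop = FALSE]
  attr(out, "index") <- idx
  out
}

#' Per-gene variance explained by a categorical covariate
#'
#' For every gene, the r-squared of an ordinary least-squares fit on the
#' one-hot-coded covariate — identical to the one-way ANOVA
#' between-group-SS / total-SS (eta squared). Constant genes get r2 = 0 by
#' convention; a constant covariate gives 0 for every gene.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param covariate per-cell categorical labels.
#' @param gene_subset optional row index restricting the genes.
#' @return named numeric vector of per-gene r-squared values.
#' @export
variance_r2 <- function(norm, covariate, gene_subset = NULL) {
  Y <- as.matrix(norm)
  if (!is.null(gene_subset)) Y <- Y[gene_subset, , drop = FALSE]
  f <- droplevels(factor(covariate))
  if (length(f) != ncol(Y)) stop("covariate must align to the cells")
  gm <- rowMeans(Y)
  tot <- rowSums((Y - gm)^2)
  if (nlevels(f) < 2)
    return(stats::setNames(rep(0, nrow(Y)), rownames(Y)))
  between <- rep(0, nrow(Y))
  for (lv in levels(f)) {
    ix <- f == lv
    between <- between + sum(ix) * (rowMeans(Y[, ix, drop = FALSE]) - gm)^2
  }
  r2 <- ifelse(tot > 0, between / tot, 0)
  stats::setNames(pmin(pmax(r2, 0), 1), rownames(Y))
}

#' Covariate-explained fraction of PC variance
#'
#' PCA on the centered matrix; the fraction is the variance-weighted mean
#' of per-PC ANOVA r-squared on the covariate over the first `n_pcs`
#' components: `sum_i var(PC_i) r2_i / sum_i var(PC_i)`.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param covariate per-cell categorical labels.
#' @param n_pcs number of leading components (default 50; truncated to the
#'   rank with a warning).
#' @return a single fraction in `[0, 1]`.
#' @export
pc_variance_fraction <- function(norm, covariate, n_pcs = 50) {
  emb <- pca_embed(norm, n_pcs = n_pcs)
  pc_var <- apply(emb, 2, stats::var)
  r2 <- variance_r2(t(emb), covariate)
  sum(pc_var * r2) / sum(pc_var)
}
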