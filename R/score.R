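#' Expression-bin-matched module score per cell
#'
#' Genes are binned into `n_bins` by their average log-normalized
#' expression; for each signature gene, `n_ctrl` control genes are drawn
#' from the non-signature genes of its bin (without replacement, with
#' replacement when the bin holds fewer than `n_ctrl`). The score of a cell
#' is the mean expression of the signature genes minus the mean expression
#' of the pooled control draws, so a positive score means the signature is
#' expressed above expression-matched background.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param signature_genes character vector; genes absent from the matrix
#'   are dropped with a warning.
#' @param n_bins number of expression bins (default 25).
#' @param n_ctrl control genes drawn per signature gene (default 100).
#' @param seed integer seed for the control draws.
#' @return named numeric per-cell score (`TimeScoreVector`) with a
#'   `provenance` attribute recording the parameters.
#' @export
module_score <- function(norm, signature_genes, n_bins = 25, n_ctrl = 100,
                         seed = 1L) {
  Y <- as.matrix(norm)
  sig <- intersect(unique(signature_genes), rownames(Y))
  if (length(sig) == 0)
    stop("no signature gene is present in the matrix")
  if (length(sig) < length(unique(signature_genes)))
    warning(sprintf("%d signature gene(s) absent from the matrix, dropped",
                    length(unique(signature_genes)) - length(sig)))
  set.seed(as.integer(seed))
  avg <- rowMeans(Y)
  n_bins_eff <- max(1L, min(n_bins, nrow(Y)))
  bin <- if (n_bins_eff == 1L) rep(1L, nrow(Y))
         else cut(rank(avg, ties.method = "first"), breaks = n_bins_eff,
                  labels = FALSE)
  nonsig <- setdiff(rownames(Y), sig)
  if (length(nonsig) == 0)
    stop("no non-signature genes available as controls")
  ctrl <- unlist(lapply(sig, function(g) {
    pool <- nonsig[bin[match(nonsig, rownames(Y))] == bin[match(g, rownames(Y))]]
    if (length(pool) == 0) pool <- nonsig
    if (length(pool) >= n_ctrl) sample(pool, n_ctrl)
    else sample(pool, n_ctrl, replace = TRUE)
  }), use.names = FALSE)
  score <- colMeans(Y[sig, , drop = FALSE]) -
    colMeans(Y[ctrl, , drop = FALSE])
  attr(score, "provenance") <- list(n_signature = length(sig),
                                    n_bins = n_bins_eff, n_ctrl = n_ctrl,
                                    seed = as.integer(seed))
  class(score) <- c("TimeScoreVector", "numeric")
  score
}

## Rank-based AUC (Mann-Whitney U / (n_pos * n_neg)), ties counted 1/2.
auc_rank <- function(x, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(x)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit a logistic model of bias status on the time score
#'
#' Unregularized maximum-likelihood logistic regression of the affected
#' flag on the per-cell score. Under perfect separation the model is still
#' returned, with coefficients capped in magnitude and a warning.
#'
#' @param scores per-cell numeric scores (e.g. [module_score()]).
#' @param labels logical/0-1 affected flags; both classes required.
#' @param coef_cap magnitude cap applied under separation (default 1e3).
#' @return `LogisticTimeModel`: list with `intercept`, `slope`,
#'   `auc_train`, `separation` flag.
#' @export
fit_classifier <- function(scores, labels, coef_cap = 1e3) {
  labels <- as.logical(labels)
  if (!any(labels) || !any(!labels)) stop("both classes must be present")
  x <- as.numeric(scores)
  ## with a single explanatory variable, perfect separation is exactly the
  ## non-overlap of the two classes' score ranges (the MLE then diverges)
  sep <- max(x[!labels]) < min(x[labels]) || max(x[labels]) < min(x[!labels])
  fit <- suppressWarnings(stats::glm(labels ~ x, family = stats::binomial()))
  beta <- stats::coef(fit)
  if (sep) {
    warning("perfect separation detected; coefficients capped")
    beta <- pmin(pmax(beta, -coef_cap), coef_cap)
  }
  ## training AUC on predicted probabilities: a signature dominated by
  ## downregulated genes gives a score that decreases with bias, which the
  ## slope sign absorbs
  prob <- stats::plogis(beta[1] + beta[2] * x)
  structure(list(intercept = unname(beta[1]), slope = unname(beta[2]),
                 auc_train = auc_rank(prob, labels), separation = sep),
            class = "LogisticTimeModel")
}

#' @method print LogisticTimeModel
#' @export
print.LogisticTimeModel <- function(x, ...) {
  cat(sprintf("LogisticTimeModel: logit(p) = %.3f + %.3f * score (training AUC %.3f%s)\n",
              x$intercept, x$slope, x$auc_train,
              if (x$separation) ", separated" else ""))
  invisible(x)
}

#' Evaluate a fitted time-score classifier
#'
#' Predicted probabilities `plogis(intercept + slope * score)`, rank-based
#' AUC (Mann-Whitney U scaled to `[0, 1]`, ties counted one half), and the
#' ROC curve evaluated at every distinct predicted probability.
#'
#' @param model a `LogisticTimeModel`.
#' @param scores,labels test-set scores and affected flags (both classes
#'   required).
#' @return list with `auc`, `prob` (per-cell predicted probability) and
#'   `roc` (data.frame `threshold`, `fpr`, `tpr`).
#' @export
predict_auc <- function(model, scores, labels) {
  stopifnot(inherits(model, "LogisticTimeModel"))
  labels <- as.logical(labels)
  if (!any(labels) || !any(!labels)) stop("both classes must be present")
  prob <- stats::plogis(model$intercept + model$slope * as.numeric(scores))
  thr <- c(Inf, sort(unique(prob), decreasing = TRUE))
  n1 <- sum(labels); n0 <- sum(!labels)
  roc <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) sum(prob >= t & !labels) / n0, 0),
    tpr = vapply(thr, function(t) sum(prob >= t & labels) / n1, 0))
  list(auc = auc_rank(prob, labels), prob = prob, roc = roc)
}

#' Regress the time score out of expression
#'
#' Per gene, ordinary least squares of log-normalized expression on the
#' per-cell score; the residuals are centered to mean zero and scaled to
#' unit variance (genes with zero residual variance become all zeros). With
#' `cell_types` given, the regression and scaling run within each cell-type
#' group independently (the Simpson's-paradox guard) and the groups are
#' reassembled in the original cell order; note that per-group
#' standardization also removes between-group mean differences, so keep the
#' default single group when between-type structure must be preserved.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param scores per-cell scores aligned to columns.
#' @param cell_types optional per-cell group labels; every group needs at
#'   least 3 cells. `NULL` treats all cells as one group.
#' @return corrected genes x cells matrix (z-scored residuals).
#' @export
regress_out_score <- function(norm, scores, cell_types = NULL) {
  Y <- as.matrix(norm)
  s <- as.numeric(scores)
  if (length(s) != ncol(Y)) stop("scores must align to the cells")
  if (is.null(cell_types)) cell_types <- rep("all", ncol(Y))
  if (length(cell_types) != ncol(Y))
    stop("cell_types must align to the cells")
  out <- matrix(0, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  for (g in unique(cell_types)) {
    idx <- which(cell_types == g)
    if (length(idx) < 3)
      stop("cell-type group '", g, "' has fewer than 3 cells")
    sc <- s[idx] - mean(s[idx])
    Yg <- Y[, idx, drop = FALSE]
    Yc <- Yg - rowMeans(Yg)
    ss <- sum(sc^2)
    resid <- if (ss > 0) Yc - tcrossprod(as.numeric(Yc %*% sc) / ss, sc)
             else Yc
    sdv <- sqrt(rowSums(resid^2) / max(length(idx) - 1L, 1L))
    ## residual variance that is numerical noise relative to the gene's
    ## own scale counts as zero (perfectly explained gene)
    sd0 <- sqrt(rowSums(Yc^2) / max(length(idx) - 1L, 1L))
    degenerate <- sdv <= 1e-10 * (sd0 + 1)
    resid <- resid / ifelse(degenerate, 1, sdv)
    resid[degenerate, ] <- 0
    out[, idx] <- resid
  }
  out
}

#' PCA embedding of cells
#'
#' Cells x `n_pcs` principal-component coordinates of the centered
#' (optionally scaled) matrix; the deterministic embedding used by the
#' silhouette and kBET diagnostics.
#'
#' @param norm genes x cells matrix.
#' @param n_pcs number of components (truncated to the rank with a warning
#'   when too large).
#' @param scale. scale genes to unit variance before PCA (default FALSE).
#' @return cells x `n_pcs` coordinate matrix.
#' @export
pca_embed <- function(norm, n_pcs = 10, scale. = FALSE) {
  X <- t(as.matrix(norm))
  max_rank <- min(dim(X)) - 1L
  if (n_pcs > max_rank) {
    warning("n_pcs exceeds the matrix rank; truncated to ", max_rank)
    n_pcs <- max_rank
  }
  if (scale.) {
    v <- apply(X, 2, stats::sd)
    X <- X[, v > 0, drop = FALSE]
  }
  pr <- stats::prcomp(X, center = TRUE, scale. = scale., rank. = n_pcs)
  pr$x[, seq_len(min(n_pcs, ncol(pr$x))), drop = FALSE]
}

#' Average silhouette width of a labeling in an embedding
#'
#' @param embedding cells x d coordinate matrix.
#' @param labels per-cell group labels (>= 2 groups).
#' @return mean silhouette width (Euclidean distance).
#' @export
avg_silhouette <- function(embedding, labels) {
  f <- factor(labels)
  if (nlevels(f) < 2) stop("silhouette needs at least 2 groups")
  sil <- cluster::silhouette(as.integer(f), stats::dist(embedding))
  mean(sil[, "sil_width"])
}

#' Bootstrap silhouette of the affected/unaffected split across bias rates
#'
#' For every affected-cell percentage in `pct_grid` and every replicate:
#' `n_cells` cells are resampled with replacement at that approximate
#' affected fraction; the average silhouette width between affected and
#' unaffected cells is computed in `n_pcs`-PC space before correction and
#' again after regressing the time score out of the resample.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param affected per-cell logical flags.
#' @param scores per-cell time scores used for the correction.
#' @param pct_grid affected percentages (default 10..90 by 10).
#' @param n_cells resample size (default 300).
#' @param reps replicates per percentage (default 25).
#' @param n_pcs PCs for the embedding (default 10).
#' @param seed integer seed.
#' @return data.frame with `pct`, `rep`, `silhouette_before`,
#'   `silhouette_after` (one row per percentage x replicate).
#' @export
bootstrap_silhouette <- function(norm, affected, scores,
                                 pct_grid = seq(10, 90, by = 10),
                                 n_cells = 300, reps = 25, n_pcs = 10,
                                 seed = 1L) {
  Y <- as.matrix(norm)
  affected <- as.logical(affected)
  s <- as.numeric(scores)
  stopifnot(length(affected) == ncol(Y), length(s) == ncol(Y))
  pos <- which(affected); neg <- which(!affected)
  if (length(pos) == 0 || length(neg) == 0)
    stop("both affected and unaffected cells are required")
  set.seed(as.integer(seed))
  rows <- vector("list", length(pct_grid) * reps)
  i <- 0L
  for (pct in pct_grid) {
    n_aff <- round(pct / 100 * n_cells)
    if (n_aff == 0 || n_aff == n_cells)
      stop("requested percentage ", pct, " leaves one class empty")
    for (r in seq_len(reps)) {
      idx <- c(sample(pos, n_aff, replace = TRUE),
               sample(neg, n_cells - n_aff, replace = TRUE))
      lab <- c(rep(TRUE, n_aff), rep(FALSE, n_cells - n_aff))
      sub <- Y[, idx, drop = FALSE]
      before <- avg_silhouette(pca_embed(sub, n_pcs), lab)
      corr <- regress_out_score(sub, s[idx])
      after <- avg_silhouette(pca_embed(corr, n_pcs), lab)
      i <- i + 1L
      rows[[i]] <- data.frame(pct = pct, rep = r,
                              silhouette_before = before,
                              silhouette_after = after)
    }
  }
  do.call(rbind, rows)
}
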