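#' Quality-control thresholds
#'
#' Explicit numeric cut-offs used by [filter_cells()] and [filter_genes()].
#' `qc_preset("smartseq2")` ships the full-length preset (minimum 75,000 and
#' maximum 1,000,000 total counts, at least 435 detected genes,
#' mitochondrial fraction below 20%, mean expression per gene of at least
#' 1); `qc_preset("droplet")` is a permissive UMI default whose values are
#' meant to be overridden after inspecting the dataset's QC distributions.
#'
#' @param min_counts,max_counts per-cell total-count window.
#' @param min_genes minimum number of detected genes per cell.
#' @param max_mito maximum mitochondrial fraction in `[0, 1]`.
#' @param min_cells_per_gene genes detected in fewer cells are dropped.
#' @param min_gene_mean genes with lower mean expression are dropped
#'   (full-length preset; 0 disables).
#' @return list of class `QcThresholds`.
#' @export
qc_thresholds <- function(min_counts = 0, max_counts = Inf, min_genes = 0,
                          max_mito = 1, min_cells_per_gene = 0,
                          min_gene_mean = 0) {
  if (!(min_counts < max_counts)) stop("min_counts must be below max_counts")
  if (max_mito < 0 || max_mito > 1) stop("max_mito must lie in [0, 1]")
  if (min_cells_per_gene < 0 || min_gene_mean < 0 || min_genes < 0)
    stop("thresholds must be nonnegative")
  structure(list(min_counts = min_counts, max_counts = max_counts,
                 min_genes = min_genes, max_mito = max_mito,
                 min_cells_per_gene = min_cells_per_gene,
                 min_gene_mean = min_gene_mean),
            class = "QcThresholds")
}

#' @rdname qc_thresholds
#' @param name `"smartseq2"` or `"droplet"`.
#' @export
qc_preset <- function(name = c("smartseq2", "droplet")) {
  switch(match.arg(name),
         smartseq2 = qc_thresholds(min_counts = 75000, max_counts = 1e6,
                                   min_genes = 435, max_mito = 0.20,
                                   min_cells_per_gene = 0,
                                   min_gene_mean = 1),
         droplet = qc_thresholds(min_counts = 500, max_counts = Inf,
                                 min_genes = 200, max_mito = 0.20,
                                 min_cells_per_gene = 10,
                                 min_gene_mean = 0))
}

#' Remove damaged cells and putative doublets by explicit thresholds
#'
#' A cell is removed when its total count falls outside
#' `[min_counts, max_counts]`, it has fewer than `min_genes` detected
#' genes, or its mitochondrial fraction exceeds `max_mito`. A cell may fail
#' several rules; the report counts both per-rule and unique removals.
#'
#' @param m a [count_matrix()].
#' @param t a [qc_thresholds()] (or preset).
#' @param mito_gene_mask logical vector aligned to genes; if `NULL`,
#'   genes are matched by `mito_prefix`.
#' @param mito_prefix gene-name prefix identifying mitochondrial genes
#'   (default `"MT-"`).
#' @return list with `matrix` (filtered `CountMatrix`) and `report`
#'   (per-rule removal counts, unique total, thresholds used).
#' @export
filter_cells <- function(m, t, mito_gene_mask = NULL, mito_prefix = "MT-") {
  stopifnot(inherits(m, "CountMatrix"), inherits(t, "QcThresholds"))
  counts <- m$counts
  if (is.null(mito_gene_mask))
    mito_gene_mask <- startsWith(rownames(counts), mito_prefix)
  if (length(mito_gene_mask) != nrow(counts))
    stop("mito_gene_mask must align to the gene index")
  totals <- Matrix::colSums(counts)
  n_genes <- Matrix::colSums(counts > 0)
  mito_frac <- if (any(mito_gene_mask))
    Matrix::colSums(counts[mito_gene_mask, , drop = FALSE]) / pmax(totals, 1)
  else rep(0, ncol(counts))

  fail_low <- totals < t$min_counts
  fail_high <- totals > t$max_counts
  fail_genes <- n_genes < t$min_genes
  fail_mito <- mito_frac > t$max_mito
  fail_any <- fail_low | fail_high | fail_genes | fail_mito
  if (all(fail_any))
    stop("QC thresholds remove every cell; inspect the QC distributions")

  report <- list(
    n_cells_in = ncol(counts),
    n_removed = sum(fail_any),
    n_kept = sum(!fail_any),
    removed_low_counts = sum(fail_low),
    removed_high_counts = sum(fail_high),
    removed_low_complexity = sum(fail_genes),
    removed_high_mito = sum(fail_mito),
    thresholds = unclass(t))
  list(matrix = subset_cells(m, cells = which(!fail_any)), report = report)
}

#' Remove genes with insufficient coverage
#'
#' Drops genes detected (nonzero) in fewer than `min_cells_per_gene` cells
#' and, when `min_gene_mean > 0`, genes whose mean raw count across cells is
#' below it (the full-length-protocol filter).
#'
#' @param m a [count_matrix()].
#' @param min_cells_per_gene detection threshold (0 disables).
#' @param min_gene_mean mean-expression threshold (0 disables).
#' @return filtered `CountMatrix`.
#' @export
filter_genes <- function(m, min_cells_per_gene = 0, min_gene_mean = 0) {
  stopifnot(inherits(m, "CountMatrix"))
  if (min_cells_per_gene < 0 || min_gene_mean < 0)
    stop("thresholds must be nonnegative")
  detected <- Matrix::rowSums(m$counts > 0)
  keep <- detected >= min_cells_per_gene
  if (min_gene_mean > 0)
    keep <- keep & Matrix::rowMeans(m$counts) >= min_gene_mean
  if (!any(keep)) stop("gene filters remove every gene")
  subset_cells(m, genes = which(keep))
}

#' Size-factor normalization to log scale
#'
#' Relative-library-size factors scaled to mean 1
#' (`sf_c = total_c / mean(total)`), then `ln(1 + count / sf)`. Any
#' downstream step that only relies on the size-factor contract (positive,
#' mean 1) can swap in pool-based deconvolution factors here.
#'
#' @param m a [count_matrix()].
#' @return a `NormalizedMatrix`: dense genes x cells matrix of
#'   log-normalized values with attributes `size_factors` (per-cell, mean
#'   1) and `cell_data` (carried over metadata).
#' @export
size_factor_normalize <- function(m) {
  stopifnot(inherits(m, "CountMatrix"))
  totals <- Matrix::colSums(m$counts)
  if (any(totals <= 0))
    stop("cells with zero total counts present; run filter_cells first")
  sf <- totals / mean(totals)
  norm <- log1p(sweep(as.matrix(m$counts), 2, sf, "/"))
  dimnames(norm) <- dimnames(m$counts)
  structure(norm, size_factors = sf, cell_data = m$cell_data,
            class = c("NormalizedMatrix", "matrix", "array"))
}

#' @method print NormalizedMatrix
#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix: %d genes x %d cells (log scale, size factors mean %.3f)\n",
              nrow(x), ncol(x), mean(attr(x, "size_factors"))))
  invisible(x)
}
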