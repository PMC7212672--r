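#' @importFrom methods as is
#' @importFrom Matrix colSums rowSums rowMeans t readMM writeMM
NULL

#' Construct a count matrix with per-cell metadata
#'
#' Bundles a sparse genes x cells UMI count matrix with a per-cell metadata
#' table (sampling time, donor, batch, temperature, cell type, ...). This is
#' the main container moved between pipeline stages.
#'
#' @param counts genes x cells matrix of nonnegative integer counts; coerced
#'   to `dgCMatrix`. Must have row (gene) and column (barcode) names.
#' @param cell_data data.frame with one row per cell, rownames matching the
#'   column names of `counts`. May be `NULL` for a bare matrix.
#' @return An object of class `CountMatrix`: a list with elements `counts`
#'   and `cell_data`.
#' @export
count_matrix <- function(counts, cell_data = NULL) {
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must carry gene rownames and barcode colnames")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("duplicate gene or barcode names in `counts`")
  if (any(counts@x < 0)) stop("counts must be nonnegative")
  if (is.null(cell_data)) {
    cell_data <- data.frame(row.names = colnames(counts))
  } else {
    cell_data <- as.data.frame(cell_data)
    if (!is.null(cell_data$barcode) && is.null(rownames(cell_data)))
      rownames(cell_data) <- cell_data$barcode
    if (!identical(rownames(cell_data), colnames(counts)))
      cell_data <- cell_data[colnames(counts), , drop = FALSE]
    if (anyNA(match(colnames(counts), rownames(cell_data))))
      stop("`cell_data` rows do not cover all barcodes in `counts`")
  }
  structure(list(counts = counts, cell_data = cell_data),
            class = "CountMatrix")
}

#' @method print CountMatrix
#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells; metadata: %s\n",
              nrow(x$counts), ncol(x$counts),
              if (ncol(x$cell_data)) paste(colnames(x$cell_data), collapse = ", ")
              else "<none>"))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Construct a hashtag (HTO) count matrix
#'
#' @param counts hashtags x barcodes matrix of nonnegative integer counts.
#' @param hto_names,barcode_ids optional dimension names; taken from
#'   `counts` when absent.
#' @return An object of class `HtoMatrix` wrapping a dense integer matrix.
#' @export
hto_matrix <- function(counts, hto_names = rownames(counts),
                       barcode_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(hto_names)) hto_names <- paste0("HTO", seq_len(nrow(counts)))
  if (is.null(barcode_ids)) barcode_ids <- paste0("BC", seq_len(ncol(counts)))
  if (anyDuplicated(hto_names)) stop("duplicate hashtag names")
  if (anyDuplicated(barcode_ids)) stop("duplicate barcode ids")
  if (!all(is.finite(counts)) || any(counts < 0))
    stop("HTO counts must be finite and nonnegative")
  dimnames(counts) <- list(hto_names, barcode_ids)
  structure(list(counts = counts), class = "HtoMatrix")
}

#' @method print HtoMatrix
#' @export
print.HtoMatrix <- function(x, ...) {
  cat(sprintf("HtoMatrix: %d hashtags x %d barcodes\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Subset a CountMatrix by genes and/or cells
#'
#' @param x a `CountMatrix`
#' @param genes,cells index vectors (logical, integer or character); `NULL`
#'   keeps everything.
#' @return the subsetted `CountMatrix`.
#' @export
subset_cells <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "CountMatrix"))
  m <- x$counts
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (!is.null(cells)) m <- m[, cells, drop = FALSE]
  count_matrix(m, x$cell_data[colnames(m), , drop = FALSE])
}
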