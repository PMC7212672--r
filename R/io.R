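#' Write a CountMatrix as a CellRanger-style MTX triplet
#'
#' Writes `matrix.mtx` (MatrixMarket, genes x cells), `features.tsv`,
#' `barcodes.tsv` and, when metadata is present, `cell_metadata.csv`
#' (columns barcode + metadata).
#'
#' @param x a `CountMatrix` (or `HtoMatrix`, written with hashtags as
#'   features).
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(x, dir) {
  if (inherits(x, "HtoMatrix"))
    x <- count_matrix(Matrix::Matrix(x$counts, sparse = TRUE))
  stopifnot(inherits(x, "CountMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  if (ncol(x$cell_data) > 0) {
    md <- cbind(barcode = rownames(x$cell_data), x$cell_data)
    utils::write.csv(md, file.path(dir, "cell_metadata.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a CellRanger-style MTX triplet into a CountMatrix
#'
#' Expects `matrix.mtx`, `features.tsv`, `barcodes.tsv` and optionally
#' `cell_metadata.csv` in `dir`.
#'
#' @param dir directory holding the triplet.
#' @return a `CountMatrix`.
#' @export
read_count_matrix <- function(dir) {
  m <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "features.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  md_path <- file.path(dir, "cell_metadata.csv")
  md <- NULL
  if (file.exists(md_path)) {
    md <- utils::read.csv(md_path, stringsAsFactors = FALSE)
    rownames(md) <- md$barcode
    md$barcode <- NULL
  }
  count_matrix(m, md)
}

#' Read gene sets from GMT or two-column TSV
#'
#' GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' TSV: two columns `term<TAB>gene`, one membership per line (header
#' optional, detected when the first line equals `term\tgene`).
#'
#' @param path file path; format chosen by extension (`.gmt` vs anything
#'   else).
#' @return named list mapping term id to a character vector of genes.
#' @export
read_gene_sets <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- vapply(parts, `[`, "", 1L)
  } else {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (identical(tolower(unlist(tab[1, ])), c("term", "gene")))
      tab <- tab[-1, , drop = FALSE]
    sets <- split(tab[[2]], tab[[1]])
    sets <- lapply(sets, unique)
  }
  if (anyDuplicated(names(sets))) stop("duplicate term ids in gene sets")
  sets
}
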