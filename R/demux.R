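#' Centered log-ratio normalization of hashtag counts
#'
#' Each hashtag's counts are divided by that hashtag's geometric mean across
#' cells and log-transformed: `clr[i, c] = ln(x[i, c] + pc) - mean_c ln(x[i, ] + pc)`.
#' The pseudocount makes zeros well-defined; every hashtag row has mean
#' exactly zero.
#'
#' @param m an [hto_matrix()] or a hashtags x barcodes numeric matrix.
#' @param pseudocount positive value added before the log (default 1).
#' @return hashtags x barcodes numeric matrix of CLR values.
#' @export
clr_normalize <- function(m, pseudocount = 1) {
  x <- if (inherits(m, "HtoMatrix")) m$counts else as.matrix(m)
  if (length(x) == 0) stop("empty HTO matrix")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  lx <- log(x + pseudocount)
  lx - rowMeans(lx)
}

#' Demultiplex hashed barcodes by k-medoids background thresholds
#'
#' Implements the cell-hashing demultiplexing procedure: (1) barcodes are
#' partitioned by k-medoids (PAM, Euclidean distance) on their CLR
#' profiles, with `k` equal to the number of pooled conditions; (2) for
#' each hashtag, the background distribution is taken as all barcodes
#' outside the cluster whose medoid is highest for that hashtag; (3) the
#' top `outlier_trim` fraction of background values is discarded as
#' outliers; (4) the per-hashtag threshold is the `q` quantile of the
#' trimmed background; (5) a barcode is assigned to the condition whose
#' threshold its CLR value strictly exceeds — to `"multiplet"` when it
#' exceeds two or more, `"negative"` when it exceeds none.
#'
#' @param clr hashtags x barcodes CLR matrix from [clr_normalize()].
#' @param k number of clusters; typically the number of conditions
#'   (`2 <= k <= n_barcodes`).
#' @param outlier_trim fraction of top background values removed (default
#'   0.005).
#' @param q background quantile defining the threshold (default 0.99,
#'   linear-interpolation sample quantile).
#' @param seed kept for interface stability; the PAM build/swap algorithm
#'   used here is deterministic.
#' @param refine when `TRUE` (default) a second thresholding pass is run
#'   with provisional multiplets removed from every background
#'   distribution. Barcodes carrying two foreground hashtags fall in some
#'   other hashtag's background and would otherwise inflate its empirical
#'   quantile, miscalling low-foreground singlets as negatives; excluding
#'   the multiplets the first pass itself detects makes the quantile
#'   robust to them. `FALSE` gives the plain single pass.
#' @return a `DemuxResult` list: `calls` (named character, one of the
#'   hashtag names, `"multiplet"` or `"negative"`), `n_exceeded` (named
#'   integer), `thresholds` (named numeric, CLR scale), `background`
#'   (hashtags x barcodes logical membership mask) and `cluster` (the PAM
#'   partition).
#' @export
demultiplex_barcodes <- function(clr, k, outlier_trim = 0.005, q = 0.99,
                                 seed = 1L, refine = TRUE) {
  clr <- as.matrix(clr)
  n <- ncol(clr)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of barcodes")
  if (is.null(rownames(clr)))
    rownames(clr) <- paste0("HTO", seq_len(nrow(clr)))
  if (is.null(colnames(clr)))
    colnames(clr) <- paste0("BC", seq_len(n))

  set.seed(as.integer(seed))
  pam_fit <- cluster::pam(t(clr), k = k, metric = "euclidean",
                          pamonce = 5, keep.diss = FALSE, keep.data = FALSE)
  clus <- pam_fit$clustering
  medoids <- pam_fit$medoids  # k x n_htos

  htos <- rownames(clr)
  thresholds <- stats::setNames(numeric(length(htos)), htos)
  background <- matrix(FALSE, nrow(clr), n, dimnames = dimnames(clr))
  multiplet <- rep(FALSE, n)
  for (pass in seq_len(if (isTRUE(refine)) 2L else 1L)) {
    for (i in seq_along(htos)) {
      fg_cluster <- which.max(medoids[, i])
      bg <- clus != fg_cluster & !multiplet
      vals <- clr[i, bg]
      if (length(vals) == 0)
        stop("hashtag ", htos[i], " has an empty background; ",
             "clustering is degenerate (try a different k)")
      cut_off <- stats::quantile(vals, 1 - outlier_trim, names = FALSE)
      trimmed <- vals[vals <= cut_off]
      if (length(trimmed) == 0)
        stop("hashtag ", htos[i], " has an empty background after trimming")
      thresholds[i] <- stats::quantile(trimmed, q, names = FALSE)
      background[i, ] <- bg
    }
    multiplet <- colSums(clr > thresholds) >= 2
  }

  exceeds <- clr > thresholds  # column-recycled: rows are HTOs
  n_exc <- colSums(exceeds)
  calls <- character(n)
  calls[n_exc == 0] <- "negative"
  calls[n_exc >= 2] <- "multiplet"
  one <- which(n_exc == 1)
  if (length(one))
    calls[one] <- htos[apply(exceeds[, one, drop = FALSE], 2, which.max)]
  names(calls) <- colnames(clr)

  structure(list(calls = calls,
                 n_exceeded = stats::setNames(as.integer(n_exc),
                                              colnames(clr)),
                 thresholds = thresholds,
                 background = background,
                 cluster = clus),
            class = "DemuxResult")
}

#' @method print DemuxResult
#' @export
print.DemuxResult <- function(x, ...) {
  tab <- table(factor(ifelse(x$calls %in% c("multiplet", "negative"),
                             x$calls, "singlet"),
                      levels = c("singlet", "multiplet", "negative")))
  cat(sprintf("DemuxResult: %d barcodes — %d singlets, %d multiplets, %d negatives\n",
              length(x$calls), tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Write demultiplexing calls and thresholds as CSV
#'
#' @param res a `DemuxResult`.
#' @param calls_path,thresholds_path output CSV paths (`thresholds_path`
#'   optional).
#' @return `calls_path`, invisibly.
#' @export
write_demux_result <- function(res, calls_path, thresholds_path = NULL) {
  utils::write.csv(data.frame(barcode = names(res$calls),
                              call = unname(res$calls),
                              n_thresholds_exceeded = unname(res$n_exceeded)),
                   calls_path, row.names = FALSE)
  if (!is.null(thresholds_path))
    utils::write.csv(data.frame(hto = names(res$thresholds),
                                threshold_clr = unname(res$thresholds)),
                     thresholds_path, row.names = FALSE)
  invisible(calls_path)
}
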