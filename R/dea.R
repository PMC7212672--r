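## Two-sample Mann-Whitney rank-sum p-value for one gene.
## Normal approximation with tie correction (no continuity correction, so
## null p-values stay close to uniform across many genes); exact
## enumeration of all C(n, n1) rank assignments when both groups have <= 8
## observations (handles ties, matches the doubled-tail convention).
mann_whitney_p <- function(x, y, exact_max = 8L) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    combs <- utils::combn(n, n1)
    sums <- colSums(matrix(r[combs], nrow = n1))
    us <- sums - n1 * (n1 + 1) / 2
    p <- 2 * min(mean(us <= u1), mean(us >= u1))
    return(min(p, 1))
  }
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (u1 - mu) / sqrt(sigma2)
  min(2 * stats::pnorm(-abs(z)), 1)
}

#' Rank-based differential expression between biased and unbiased cells
#'
#' For every gene, a two-sided Mann-Whitney rank-sum test compares
#' log-normalized expression between the two cell groups (typically
#' time-biased, sampled more than 2 h after extraction, versus unbiased).
#' The log fold-change is computed on de-logged group means with a
#' pseudocount: `lfc = ln(mean(expm1(x_biased)) + pc) - ln(mean(expm1(x_unbiased)) + pc)`
#' (natural log).
#'
#' @param norm a `NormalizedMatrix` from [size_factor_normalize()], or any
#'   genes x cells matrix of log-normalized values.
#' @param biased_mask logical per-cell vector (`TRUE` = biased group); both
#'   groups must be non-empty.
#' @param adjust multiple-testing adjustment, `"bonferroni"` (default) or
#'   `"BH"`.
#' @param lfc_pseudocount pseudocount in the fold-change formula.
#' @return a `DeaTable` data.frame: `gene`, `mean_biased`, `mean_unbiased`
#'   (group means on the log scale), `logFC`, `p`, `p_adj`, `direction`
#'   (`"up"`/`"down"`/`"none"` by sign of `logFC`).
#' @export
wilcoxon_dea <- function(norm, biased_mask, adjust = c("bonferroni", "BH"),
                         lfc_pseudocount = 1) {
  adjust <- match.arg(adjust)
  Y <- as.matrix(norm)
  biased_mask <- as.logical(biased_mask)
  if (length(biased_mask) != ncol(Y))
    stop("biased_mask must align to the cells")
  if (!any(biased_mask) || !any(!biased_mask))
    stop("both groups must be non-empty")

  a <- which(biased_mask); b <- which(!biased_mask)
  p <- apply(Y, 1L, function(v) mann_whitney_p(v[a], v[b]))
  mean_a <- rowMeans(Y[, a, drop = FALSE])
  mean_b <- rowMeans(Y[, b, drop = FALSE])
  lfc <- log(rowMeans(expm1(Y[, a, drop = FALSE])) + lfc_pseudocount) -
    log(rowMeans(expm1(Y[, b, drop = FALSE])) + lfc_pseudocount)
  res <- data.frame(
    gene = if (!is.null(rownames(Y))) rownames(Y) else
      sprintf("gene%d", seq_len(nrow(Y))),
    mean_biased = mean_a,
    mean_unbiased = mean_b,
    logFC = lfc,
    p = p,
    p_adj = stats::p.adjust(p, method = adjust),
    direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none")),
    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("DeaTable", "data.frame")
  res
}

#' Filter a DEA table into a sampling-time signature
#'
#' Keeps genes with `|logFC| >= min_abs_logfc`, adjusted p below
#' `max_adj_p`, and larger-group mean log expression of at least
#' `min_expr`; orders by adjusted p, then by absolute fold-change.
#'
#' @param dea a `DeaTable` from [wilcoxon_dea()].
#' @param min_abs_logfc minimum absolute log fold-change (default 0.25).
#' @param max_adj_p adjusted-p cut-off, strict (default 0.001).
#' @param min_expr minimum of the larger group mean on the log scale
#'   (default 0, disabled).
#' @return a `SignatureTable` data.frame (subset of the DEA columns) with
#'   the thresholds recorded in `attr(, "provenance")`.
#' @export
define_signature <- function(dea, min_abs_logfc = 0.25, max_adj_p = 0.001,
                             min_expr = 0) {
  if (min_abs_logfc < 0 || max_adj_p < 0 || min_expr < 0)
    stop("thresholds must be nonnegative")
  keep <- abs(dea$logFC) >= min_abs_logfc &
    dea$p_adj < max_adj_p &
    pmax(dea$mean_biased, dea$mean_unbiased) >= min_expr
  sig <- dea[keep, , drop = FALSE]
  sig <- sig[order(sig$p_adj, -abs(sig$logFC)), , drop = FALSE]
  rownames(sig) <- NULL
  attr(sig, "provenance") <- list(min_abs_logfc = min_abs_logfc,
                                  max_adj_p = max_adj_p,
                                  min_expr = min_expr)
  class(sig) <- c("SignatureTable", "data.frame")
  sig
}

#' Hypergeometric over-representation of gene sets
#'
#' For every term, an upper-tail hypergeometric test of the overlap between
#' the target list and the term's genes within the universe, plus the
#' sample odds ratio of the 2x2 table (Haldane correction of 0.5 added to
#' every cell when any cell is zero). Terms are size-filtered before
#' testing: too-specific terms (`size < min_size`) and too-general ones
#' (`size >= max_size_exclusive`) are dropped; sizes count universe genes
#' only.
#'
#' @param target_genes character vector; must be a subset of
#'   `universe_genes`.
#' @param universe_genes character vector of all genes considered.
#' @param gene_sets named list term -> gene vector (see
#'   [read_gene_sets()]).
#' @param min_size,max_size_exclusive term-size window (defaults 3 and
#'   600).
#' @param max_p retain terms with `p < max_p` (default 0.05).
#' @param min_or retain terms with odds ratio `> min_or` (default 2).
#' @return data.frame with `term`, `size`, `overlap`, `p`, `odds_ratio`,
#'   `genes` (comma-separated overlap), ordered by p.
#' @export
set_enrichment <- function(target_genes, universe_genes, gene_sets,
                           min_size = 3, max_size_exclusive = 600,
                           max_p = 0.05, min_or = 2) {
  target_genes <- unique(target_genes)
  universe_genes <- unique(universe_genes)
  stray <- setdiff(target_genes, universe_genes)
  if (length(stray))
    stop("target genes missing from the universe: ",
         paste(utils::head(stray, 5), collapse = ", "),
         if (length(stray) > 5) ", ..." else "")
  N <- length(universe_genes)
  n_t <- length(target_genes)
  rows <- lapply(names(gene_sets), function(term) {
    set <- intersect(gene_sets[[term]], universe_genes)
    size <- length(set)
    if (size < min_size || size >= max_size_exclusive) return(NULL)
    hit <- intersect(target_genes, set)
    k <- length(hit)
    p <- stats::phyper(k - 1, size, N - size, n_t, lower.tail = FALSE)
    a <- k; b <- n_t - k; cc <- size - k; d <- N - size - n_t + k
    if (min(a, b, cc, d) == 0) { a <- a + 0.5; b <- b + 0.5
                                 cc <- cc + 0.5; d <- d + 0.5 }
    data.frame(term = term, size = size, overlap = k, p = p,
               odds_ratio = (a * d) / (b * cc),
               genes = paste(hit, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(), size = integer(),
                      overlap = integer(), p = numeric(),
                      odds_ratio = numeric(), genes = character()))
  out <- out[out$p < max_p & out$odds_ratio > min_or, , drop = FALSE]
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap between two gene signatures
#'
#' Optionally truncates each list to its `top_n` entries by absolute
#' ranking value (e.g., log fold-change) before intersecting — the device
#' used to harmonize differently sized published signatures.
#'
#' @param sig_a,sig_b `SignatureTable`s, or character vectors of genes, or
#'   named numeric vectors (names = genes, values = ranking).
#' @param top_n optional truncation size; requires ranking values.
#' @return list with `intersection`, `jaccard`, `n_a`, `n_b`, and — when
#'   both signatures carry directions — `shared_up`, `shared_down` counts.
#' @export
signature_overlap <- function(sig_a, sig_b, top_n = NULL) {
  extract <- function(s) {
    if (inherits(s, "data.frame"))
      list(genes = s$gene, rank_val = s$logFC,
           dir = if ("direction" %in% names(s)) s$direction else NULL)
    else if (is.numeric(s) && !is.null(names(s)))
      list(genes = names(s), rank_val = unname(s), dir = NULL)
    else
      list(genes = as.character(s), rank_val = NULL, dir = NULL)
  }
  a <- extract(sig_a); b <- extract(sig_b)
  if (!is.null(top_n)) {
    if (is.null(a$rank_val) || is.null(b$rank_val))
      stop("top_n truncation requires ranking values (logFC or named vector)")
    take <- function(s) {
      ord <- order(-abs(s$rank_val))[seq_len(min(top_n, length(s$genes)))]
      lapply(s, function(f) if (is.null(f)) NULL else f[ord])
    }
    a <- take(a); b <- take(b)
  }
  inter <- intersect(a$genes, b$genes)
  uni <- union(a$genes, b$genes)
  out <- list(intersection = inter,
              jaccard = if (length(uni)) length(inter) / length(uni) else NA_real_,
              n_a = length(a$genes), n_b = length(b$genes))
  if (!is.null(a$dir) && !is.null(b$dir)) {
    da <- stats::setNames(a$dir, a$genes)[inter]
    db <- stats::setNames(b$dir, b$genes)[inter]
    out$shared_up <- sum(da == "up" & db == "up")
    out$shared_down <- sum(da == "down" & db == "down")
  }
  out
}
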