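# Small fixtures built in code, shared across test files.

# genes x cells CountMatrix from a dense matrix (names auto-filled)
toy_counts <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  count_matrix(Matrix::Matrix(m, sparse = TRUE))
}

# clearly bimodal 2-HTO CLR matrix: `n_per` singlets per hashtag,
# jittered foreground ~ +2 over a flat background at -2 (flat so the
# strict exceedance rule has a margin over the background quantile)
toy_bimodal_clr <- function(n_per = 30, fg = 2, bg = -2, jitter = 0.05) {
  n <- 2 * n_per
  set.seed(99)
  clr <- matrix(bg, 2, n)
  clr[1, seq_len(n_per)] <- fg + stats::runif(n_per, -jitter, jitter)
  clr[2, n_per + seq_len(n_per)] <- fg + stats::runif(n_per, -jitter, jitter)
  dimnames(clr) <- list(c("HTO1", "HTO2"), paste0("bc", seq_len(n)))
  clr
}

# type-7 sample quantile computed by explicit sort-and-index, kept
# independent of stats::quantile for use as an oracle
sort_index_quantile <- function(v, p) {
  s <- sort(unname(v))
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  if (lo == length(s)) return(s[lo])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

# two-sided Mann-Whitney p by exhaustive enumeration of label assignments
enum_mw_p <- function(x, y) {
  n1 <- length(x)
  pool <- c(x, y)
  r <- rank(pool)
  obs <- sum(r[seq_len(n1)])
  sums <- colSums(matrix(r[utils::combn(length(pool), n1)], nrow = n1))
  min(1, 2 * min(mean(sums <= obs), mean(sums >= obs)))
}

# AUC by direct concordant-pair counting (ties count one half)
pair_auc <- function(x, labels) {
  labels <- as.logical(labels)
  pos <- x[labels]; neg <- x[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
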