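#' Configuration for the count simulator
#'
#' Builds a validated configuration for [simulate_counts()]. Defaults emulate
#' a PBMC-like benchmarking experiment: several sampling-time conditions, a
#' handful of cell types with marker genes, a large fraction of genes under
#' monotone time-dependent downregulation, a small up-regulated cold-shock
#' module, library-size decay over time, and multiplicative donor/batch
#' effects.
#'
#' @param n_genes number of genes.
#' @param n_cells_per_condition cells simulated per sampling-time condition.
#' @param conditions sampling times in hours (ordered labels).
#' @param n_cell_types number of cell types (marker-driven).
#' @param n_markers_per_type marker genes elevated in each type.
#' @param marker_fc multiplicative elevation of a marker in its own type.
#' @param downreg_fraction fraction of genes whose means decay with time.
#' @param downreg_rate per-hour multiplicative decay rate on affected genes
#'   (mean scaled by `exp(-downreg_rate * t)`).
#' @param coldshock_genes number of genes in the up-regulated cold-shock
#'   module (CIRBP/RBM3-like behaviour).
#' @param coldshock_rate per-hour multiplicative gain on cold-shock genes.
#' @param base_mean_shape,base_mean_scale gamma parameters for baseline gene
#'   means.
#' @param dispersion negative-binomial size parameter (smaller = noisier).
#' @param libsize_decay per-hour scaling of per-cell library size.
#' @param libsize_sd log-normal sd of per-cell library-size noise.
#' @param donor_sd,batch_sd log-normal sd of gene-wise multiplicative donor
#'   and batch effects.
#' @param n_donors,n_batches number of donors/batches, assigned round-robin
#'   within each condition so conditions stay balanced.
#' @param temperature storage-temperature label recorded in metadata.
#' @param seed integer seed; identical seed + config gives bit-identical
#'   output.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_cells_per_condition = 250,
                       conditions = c(0, 2, 8, 24),
                       n_cell_types = 4,
                       n_markers_per_type = 20,
                       marker_fc = 8,
                       downreg_fraction = 0.3,
                       downreg_rate = 0.05,
                       coldshock_genes = 20,
                       coldshock_rate = 0.05,
                       base_mean_shape = 0.6,
                       base_mean_scale = 1.5,
                       dispersion = 2,
                       libsize_decay = 0.02,
                       libsize_sd = 0.1,
                       donor_sd = 0.1,
                       batch_sd = 0.05,
                       n_donors = 2,
                       n_batches = 2,
                       temperature = "RT",
                       seed = 1L) {
  cfg <- as.list(environment())
  num <- cfg[setdiff(names(cfg), "temperature")]
  if (!all(vapply(num, function(v) is.numeric(v) && all(is.finite(v)), TRUE)))
    stop("simulation configuration error: all numeric fields must be finite")
  if (any(unlist(num) < 0))
    stop("simulation configuration error: negative parameter")
  if (cfg$n_genes < 1 || cfg$n_cells_per_condition < 1 ||
      length(cfg$conditions) < 1)
    stop("simulation configuration error: empty design")
  if (cfg$downreg_fraction > 1)
    stop("simulation configuration error: downreg_fraction > 1")
  if (cfg$downreg_fraction + cfg$coldshock_genes / cfg$n_genes > 1)
    stop("simulation configuration error: ",
         "downreg_fraction + cold-shock fraction exceeds 1")
  if (cfg$n_cell_types * cfg$n_markers_per_type > cfg$n_genes)
    stop("simulation configuration error: more marker genes than genes")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a UMI count matrix with planted sampling-time structure
#'
#' Gamma-Poisson (negative binomial) counts. For a cell sampled at time `t`,
#' affected genes have their mean scaled by `exp(-downreg_rate * t)` and
#' cold-shock genes by `exp(+coldshock_rate * t)`; each cell type's marker
#' genes are elevated `marker_fc`-fold in that type; library size decays as
#' `exp(-libsize_decay * t)`; donor and batch act as gene-wise log-normal
#' multipliers. Full ground truth is returned for downstream validation.
#'
#' @param config a [sim_config()].
#' @return list with elements
#'   \describe{
#'     \item{matrix}{a [count_matrix()] with metadata columns `time_h`,
#'       `donor`, `batch`, `temperature`, `cell_type`, `affected`
#'       (`TRUE` iff `time_h > 2`).}
#'     \item{truth}{list with `cell` (per-cell design) and `gene`
#'       (per-gene planted `direction` in down/up/null and `true_lfc`,
#'       the natural-log expected fold-change between the affected and
#'       unaffected groups).}
#'   }
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  times <- rep(config$conditions, each = config$n_cells_per_condition)
  N <- length(times)

  gene_ids <- sprintf("gene%04d", seq_len(G))
  barcodes <- sprintf("cell%05d", seq_len(N))

  ## per-cell design: round-robin donors/batches within condition keeps the
  ## design balanced so conditions are exchangeable when all rates are zero
  within <- unlist(lapply(table(times)[as.character(unique(times))],
                          seq_len), use.names = FALSE)
  donor <- paste0("donor", (within - 1L) %% config$n_donors + 1L)
  batch <- paste0("batch", ((within - 1L) %/% config$n_donors) %%
                    config$n_batches + 1L)
  cell_type <- paste0("type", sample.int(config$n_cell_types, N,
                                         replace = TRUE))

  ## gene roles
  mu <- stats::rgamma(G, shape = config$base_mean_shape,
                      scale = config$base_mean_scale)
  mu <- pmax(mu, 1e-4)
  n_marker <- config$n_cell_types * config$n_markers_per_type
  marker_of <- rep(NA_integer_, G)
  if (n_marker > 0) {
    marker_idx <- sample.int(G, n_marker)
    marker_of[marker_idx] <- rep(seq_len(config$n_cell_types),
                                 each = config$n_markers_per_type)
    mu[marker_idx] <- pmax(mu[marker_idx], 0.5)  # markers must be detectable
  }
  free <- which(is.na(marker_of))
  n_cold <- min(config$coldshock_genes, length(free))
  cold_idx <- if (n_cold > 0) sample(free, n_cold) else integer(0)
  free <- setdiff(free, cold_idx)
  n_down <- min(round(config$downreg_fraction * G), length(free))
  down_idx <- if (n_down > 0) sample(free, n_down) else integer(0)

  rate <- numeric(G)
  rate[down_idx] <- -config$downreg_rate
  rate[cold_idx] <- config$coldshock_rate

  ## gene x donor and gene x batch log-normal multipliers
  donor_mult <- matrix(stats::rlnorm(G * config$n_donors,
                                     sdlog = config$donor_sd),
                       G, config$n_donors)
  batch_mult <- matrix(stats::rlnorm(G * config$n_batches,
                                     sdlog = config$batch_sd),
                       G, config$n_batches)

  lib <- exp(-config$libsize_decay * times) *
    stats::rlnorm(N, sdlog = config$libsize_sd)

  di <- as.integer(sub("donor", "", donor))
  bi <- as.integer(sub("batch", "", batch))
  ti <- as.integer(sub("type", "", cell_type))

  M <- outer(mu, lib)                                # G x N baseline
  M <- M * exp(outer(rate, times))                   # planted time effects
  M <- M * donor_mult[, di] * batch_mult[, bi]
  if (n_marker > 0) {
    boost <- matrix(1, G, N)
    mk <- which(!is.na(marker_of))
    boost[mk, ] <- ifelse(outer(marker_of[mk], ti, "=="), config$marker_fc, 1)
    M <- M * boost
  }

  counts <- matrix(stats::rnbinom(G * N, mu = as.vector(M),
                                  size = config$dispersion), G, N)
  dimnames(counts) <- list(gene_ids, barcodes)

  affected <- times > 2
  cell_data <- data.frame(time_h = times, donor = donor, batch = batch,
                          temperature = config$temperature,
                          cell_type = cell_type, affected = affected,
                          row.names = barcodes)

  ## expected natural-log fold-change for the affected vs unaffected contrast
  dt <- if (any(affected) && any(!affected))
    mean(times[affected]) - mean(times[!affected]) else 0
  gene_truth <- data.frame(
    gene = gene_ids,
    direction = ifelse(rate < 0, "down", ifelse(rate > 0, "up", "null")),
    rate_per_h = rate,
    true_lfc = rate * dt,
    marker_of = ifelse(is.na(marker_of), "", paste0("type", marker_of)),
    stringsAsFactors = FALSE)

  list(matrix = count_matrix(Matrix::Matrix(counts, sparse = TRUE), cell_data),
       truth = list(cell = cell_data, gene = gene_truth))
}

#' Simulate a hashtag-oligo (HTO) count matrix with ground truth
#'
#' Singlet barcodes draw their own hashtag's counts from a foreground
#' negative binomial and all other hashtags from a background one; doublets
#' draw foreground for two distinct hashtags; negatives draw background
#' everywhere.
#'
#' @param n_barcodes,n_htos matrix dimensions (`n_htos >= 2`).
#' @param fg_mean,bg_mean negative-binomial means of foreground/background
#'   (`fg_mean > bg_mean >= 0`).
#' @param dispersion NB size parameter shared by both components.
#' @param doublet_rate,negative_rate proportions in `[0, 1)`.
#' @param seed integer seed.
#' @return list with `matrix` (an [hto_matrix()]) and `truth` (data.frame
#'   with per-barcode `call` — an HTO name, `"doublet"` or `"negative"` —
#'   and the contributing hashtags `hto1`, `hto2`).
#' @export
simulate_hto <- function(n_barcodes, n_htos, fg_mean = 200, bg_mean = 5,
                         dispersion = 10, doublet_rate = 0.05,
                         negative_rate = 0.02, seed = 1L) {
  if (n_htos < 2) stop("n_htos must be >= 2")
  if (!(fg_mean > bg_mean && bg_mean >= 0))
    stop("need fg_mean > bg_mean >= 0")
  if (doublet_rate < 0 || doublet_rate >= 1 ||
      negative_rate < 0 || negative_rate >= 1 ||
      doublet_rate + negative_rate >= 1)
    stop("rates must lie in [0, 1) and sum below 1")
  set.seed(as.integer(seed))

  hto_names <- paste0("HTO", seq_len(n_htos))
  barcodes <- sprintf("bc%05d", seq_len(n_barcodes))
  u <- stats::runif(n_barcodes)
  kind <- ifelse(u < doublet_rate, "doublet",
                 ifelse(u < doublet_rate + negative_rate, "negative",
                        "singlet"))
  hto1 <- rep(NA_integer_, n_barcodes)
  hto2 <- rep(NA_integer_, n_barcodes)
  sing <- kind == "singlet"
  hto1[sing] <- sample.int(n_htos, sum(sing), replace = TRUE)
  dbl <- which(kind == "doublet")
  for (i in dbl) {
    pair <- sample.int(n_htos, 2L)
    hto1[i] <- pair[1L]; hto2[i] <- pair[2L]
  }

  fg <- matrix(FALSE, n_htos, n_barcodes)
  fg[cbind(hto1[!is.na(hto1)], which(!is.na(hto1)))] <- TRUE
  fg[cbind(hto2[!is.na(hto2)], which(!is.na(hto2)))] <- TRUE
  counts <- matrix(stats::rnbinom(n_htos * n_barcodes,
                                  mu = ifelse(fg, fg_mean, bg_mean),
                                  size = dispersion),
                   n_htos, n_barcodes)

  truth <- data.frame(
    barcode = barcodes,
    call = ifelse(kind == "singlet", hto_names[hto1], kind),
    hto1 = ifelse(is.na(hto1), "", hto_names[hto1]),
    hto2 = ifelse(is.na(hto2), "", hto_names[hto2]),
    stringsAsFactors = FALSE)

  list(matrix = hto_matrix(counts, hto_names, barcodes), truth = truth)
}
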