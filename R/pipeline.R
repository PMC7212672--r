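#' Default pipeline configuration
#'
#' A nested list covering every stage of the sampling-time pipeline:
#' simulation, HTO demultiplexing, QC/normalization, differential
#' expression and signature, time-score classification, regression
#' correction, and mixing/variance diagnostics. One global seed; every
#' stochastic stage derives its own stream from it. The simulation block
#' defaults are the planted-effect study conditions (two donors, 0 h vs
#' 24 h, 30% of genes decaying at 0.05/h); the bootstrap stage is off by
#' default because it dominates the runtime.
#'
#' @param seed global integer seed.
#' @return nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = NULL,
    stages = list(demux = TRUE, correct = TRUE, variance = TRUE,
                  bootstrap = FALSE),
    sim = list(n_genes = 2000, n_cells_per_condition = 500,
               conditions = c(0, 24), n_cell_types = 4,
               n_markers_per_type = 20, downreg_fraction = 0.3,
               downreg_rate = 0.05, coldshock_genes = 20,
               coldshock_rate = 0.05, n_donors = 2),
    hto = list(n_barcodes = 2000, n_htos = 4, fg_mean = 200, bg_mean = 5,
               dispersion = 10, doublet_rate = 0.05, negative_rate = 0.02),
    demux = list(outlier_trim = 0.005, q = 0.99),
    qc = list(min_counts = 100, max_counts = Inf, min_genes = 50,
              max_mito = 0.2, min_cells_per_gene = 10, min_gene_mean = 0),
    dea = list(min_abs_logfc = 0.25, max_adj_p = 0.001,
               adjust = "bonferroni"),
    score = list(n_bins = 25, n_ctrl = 100),
    train_donor = "donor1",
    test_donor = "donor2",
    n_pcs = 10,
    bootstrap = list(pct_grid = seq(10, 90, by = 10), n_cells = 300,
                     reps = 25))
}

#' Read a pipeline configuration from YAML
#'
#' Values found in the file override [default_run_config()]; unknown keys
#' are rejected.
#'
#' @param path YAML file.
#' @param seed optional seed overriding both the default and the file.
#' @return merged configuration list.
#' @export
read_run_config <- function(path, seed = NULL) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  merge_into <- function(base, over, where = "") {
    for (k in names(over)) {
      if (!k %in% names(base))
        stop("unknown configuration key: ", where, k)
      if (is.list(base[[k]]) && is.list(over[[k]]))
        base[[k]] <- merge_into(base[[k]], over[[k]],
                                paste0(where, k, "."))
      else base[[k]] <- over[[k]]
    }
    base
  }
  cfg <- merge_into(cfg, user)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

#' Run the full sampling-time artifact pipeline
#'
#' Executes simulate -> demux -> qc/normalize -> DEA/signature ->
#' score/classify -> correct -> mixing/variance in dependency order on a
#' simulated dataset with known ground truth, and returns a report of
#' headline metrics (all regenerable from config + seed). When
#' `config$out_dir` is set, intermediate artifacts (MTX triplet, DEA and
#' signature TSV, scores CSV, JSON report) are written per stage.
#'
#' @param config a configuration list from [default_run_config()] or
#'   [read_run_config()].
#' @return `RunReport` list with per-stage dimensions, parameters and
#'   headline metrics.
#' @export
run_pipeline <- function(config = default_run_config()) {
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  report <- list(seed = seed, stages = list())
  t0 <- Sys.time()

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## --- simulate -------------------------------------------------------
  sim <- run_stage("simulate", {
    sim_cfg <- do.call(sim_config, c(config$sim, list(seed = seed)))
    simulate_counts(sim_cfg)
  })
  report$stages$simulate <- list(
    n_genes = nrow(sim$matrix$counts), n_cells = ncol(sim$matrix$counts),
    conditions = unique(sim$matrix$cell_data$time_h))
  if (!is.null(out_dir))
    write_count_matrix(sim$matrix, file.path(out_dir, "counts"))

  ## --- demux (HTO pathway, simulated alongside) -----------------------
  if (isTRUE(config$stages$demux)) {
    demux_metrics <- run_stage("demux", {
      hto <- do.call(simulate_hto, c(config$hto, list(seed = seed + 1L)))
      clr <- clr_normalize(hto$matrix)
      res <- demultiplex_barcodes(clr, k = config$hto$n_htos,
                                  outlier_trim = config$demux$outlier_trim,
                                  q = config$demux$q, seed = seed + 2L)
      truth <- hto$truth
      singlet <- !truth$call %in% c("doublet", "negative")
      if (!is.null(out_dir))
        write_demux_result(res, file.path(out_dir, "demux_calls.csv"),
                           file.path(out_dir, "demux_thresholds.csv"))
      list(singlet_accuracy = mean(res$calls[singlet] ==
                                     truth$call[singlet]),
           doublet_recall = if (any(truth$call == "doublet"))
             mean(res$calls[truth$call == "doublet"] == "multiplet")
           else NA_real_,
           n_barcodes = length(res$calls))
    })
    report$stages$demux <- demux_metrics
  }

  ## --- qc + normalize -------------------------------------------------
  norm <- run_stage("qc", {
    thr <- qc_thresholds(min_counts = config$qc$min_counts,
                         max_counts = config$qc$max_counts,
                         min_genes = config$qc$min_genes,
                         max_mito = config$qc$max_mito)
    fc <- filter_cells(sim$matrix, thr)
    fg <- filter_genes(fc$matrix, config$qc$min_cells_per_gene,
                       config$qc$min_gene_mean)
    report$stages$qc <- c(fc$report[c("n_cells_in", "n_removed", "n_kept")],
                           list(n_genes_kept = nrow(fg$counts)))
    if (!is.null(out_dir)) write_count_matrix(fg, file.path(out_dir, "qc"))
    size_factor_normalize(fg)
  })
  meta <- attr(norm, "cell_data")
  affected <- meta$affected

  ## --- DEA + signature on the training donor --------------------------
  train <- meta$donor == config$train_donor
  test <- meta$donor == config$test_donor
  if (!any(train) || !any(test))
    stop("pipeline stage 'dea' failed: train/test donors not found")
  sig <- run_stage("dea", {
    dea <- wilcoxon_dea(norm[, train, drop = FALSE], affected[train],
                        adjust = config$dea$adjust)
    s <- define_signature(dea, min_abs_logfc = config$dea$min_abs_logfc,
                          max_adj_p = config$dea$max_adj_p)
    if (!is.null(out_dir)) {
      utils::write.table(dea, file.path(out_dir, "dea.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      utils::write.table(as.data.frame(s),
                         file.path(out_dir, "signature.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
    s
  })
  report$stages$dea <- list(n_signature_genes = nrow(sig),
                            n_up = sum(sig$direction == "up"),
                            n_down = sum(sig$direction == "down"))
  if (nrow(sig) == 0)
    stop("pipeline stage 'dea' failed: empty signature; ",
         "no time effect detectable under this configuration")

  ## --- time score + cross-donor classification ------------------------
  cls <- run_stage("score", {
    score <- module_score(norm, sig$gene, n_bins = config$score$n_bins,
                          n_ctrl = config$score$n_ctrl, seed = seed + 3L)
    model <- fit_classifier(score[train], affected[train])
    pred <- predict_auc(model, score[test], affected[test])
    ## random-gene control signature of the same size
    set.seed(seed + 4L)
    rand_genes <- sample(rownames(norm), nrow(sig))
    rand_score <- module_score(norm, rand_genes,
                               n_bins = config$score$n_bins,
                               n_ctrl = config$score$n_ctrl,
                               seed = seed + 5L)
    rand_model <- fit_classifier(rand_score[train], affected[train])
    rand_pred <- predict_auc(rand_model, rand_score[test], affected[test])
    if (!is.null(out_dir))
      utils::write.csv(
        data.frame(barcode = colnames(norm), score = as.numeric(score),
                   prob_biased = stats::plogis(model$intercept +
                                                 model$slope * score),
                   affected = affected),
        file.path(out_dir, "scores.csv"), row.names = FALSE)
    list(score = score, model = model, test_auc = pred$auc,
         random_signature_auc = rand_pred$auc)
  })
  report$stages$score <- list(train_auc = cls$model$auc_train,
                              test_auc = cls$test_auc,
                              random_signature_auc = cls$random_signature_auc)

  ## --- correction + mixing diagnostics --------------------------------
  if (isTRUE(config$stages$correct)) {
    mix <- run_stage("correct", {
      corrected <- regress_out_score(norm, cls$score)
      emb_before <- pca_embed(norm, config$n_pcs)
      emb_after <- pca_embed(corrected, config$n_pcs)
      time_lab <- meta$time_h
      list(
        silhouette_before = avg_silhouette(emb_before, affected),
        silhouette_after = avg_silhouette(emb_after, affected),
        celltype_silhouette_before = avg_silhouette(emb_before,
                                                    meta$cell_type),
        celltype_silhouette_after = avg_silhouette(emb_after,
                                                   meta$cell_type),
        kbet_acceptance_before = kbet(emb_before, time_lab,
                                      seed = seed + 6L)$acceptance_rate,
        kbet_acceptance_after = kbet(emb_after, time_lab,
                                     seed = seed + 6L)$acceptance_rate)
    })
    report$stages$correct <- mix
  }

  ## --- variance attribution -------------------------------------------
  if (isTRUE(config$stages$variance)) {
    report$stages$variance <- run_stage("variance", {
      list(
        time_pc_variance_fraction =
          pc_variance_fraction(norm, meta$time_h, n_pcs = config$n_pcs),
        median_r2 = lapply(
          list(time = meta$time_h, donor = meta$donor, batch = meta$batch,
               cell_type = meta$cell_type),
          function(cv) stats::median(variance_r2(norm, cv))))
    })
  }

  ## --- bootstrap silhouette (optional, slow) --------------------------
  if (isTRUE(config$stages$bootstrap)) {
    report$stages$bootstrap <- run_stage("bootstrap", {
      bt <- bootstrap_silhouette(norm, affected, cls$score,
                                 pct_grid = config$bootstrap$pct_grid,
                                 n_cells = config$bootstrap$n_cells,
                                 reps = config$bootstrap$reps,
                                 n_pcs = config$n_pcs, seed = seed + 7L)
      if (!is.null(out_dir))
        utils::write.csv(bt, file.path(out_dir, "bootstrap_silhouette.csv"),
                         row.names = FALSE)
      list(n_rows = nrow(bt),
           mean_before = mean(bt$silhouette_before),
           mean_after = mean(bt$silhouette_after))
    })
  }

  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  class(report) <- "RunReport"
  if (!is.null(out_dir)) {
    rep_out <- report
    rep_out$stages$score$score <- NULL
    jsonlite::write_json(unclass(rep_out),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @method print RunReport
#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport (seed", x$seed, ")\n")
  if (!is.null(x$stages$simulate))
    cat(sprintf("  simulated: %d genes x %d cells\n",
                x$stages$simulate$n_genes, x$stages$simulate$n_cells))
  if (!is.null(x$stages$demux))
    cat(sprintf("  demux: singlet accuracy %.3f, doublet recall %.3f\n",
                x$stages$demux$singlet_accuracy,
                x$stages$demux$doublet_recall))
  if (!is.null(x$stages$dea))
    cat(sprintf("  signature: %d genes (%d up, %d down)\n",
                x$stages$dea$n_signature_genes, x$stages$dea$n_up,
                x$stages$dea$n_down))
  if (!is.null(x$stages$score))
    cat(sprintf("  AUC: train %.3f, test %.3f (random-gene control %.3f)\n",
                x$stages$score$train_auc, x$stages$score$test_auc,
                x$stages$score$random_signature_auc))
  if (!is.null(x$stages$correct))
    cat(sprintf("  silhouette %.3f -> %.3f; kBET acceptance %.1f%% -> %.1f%%\n",
                x$stages$correct$silhouette_before,
                x$stages$correct$silhouette_after,
                x$stages$correct$kbet_acceptance_before,
                x$stages$correct$kbet_acceptance_after))
  invisible(x)
}
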