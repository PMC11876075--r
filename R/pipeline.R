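# End-to-end orchestration of the synthetic-data pipeline: simulate ->
# atlas -> motif catalog -> ridge models -> integration statistics ->
# clonal overlap, with plain-text TSV outputs and a machine-readable run
# manifest. Every stage draws from a per-component stream derived from the
# single config seed, so reruns are byte-identical.

#' Run the full pipeline on synthetic data
#'
#' Executes every stage against a generated dataset with planted ground
#' truth: builds and filters the peak atlas from simulated replicate peak
#' calls, constructs the motif catalog and the binary peak-by-motif matrix
#' from simulated sequences, fits the svn/svr ridge models with
#' leave-one-motif-out delta-correlation attribution, runs the bulk
#' clustering and single-cell integration statistics, and the clonotype
#' overlap analysis.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional directory; when given, stage outputs are
#'   written as TSVs plus a `manifest.json`.
#' @param delta_cor_groups Motif groups (indices) whose peak subsets get a
#'   delta-correlation report; default the planted groups.
#' @return A list of per-stage results (see the pipeline vignette).
#' @export
run_pipeline <- function(cfg = sim_config(), out_dir = NULL,
                         delta_cor_groups = NULL) {
  log_stage <- function(...) message("[ridgemotif] ", ...)

  log_stage("simulate: peak calls")
  sim_peaks <- simulate_peak_calls(cfg)
  peaks <- do.call(rbind, lapply(sim_peaks$peaks, function(p) {
    p[, setdiff(names(p), "locus")]
  }))

  log_stage("atlas: cluster, merge, filter")
  atlas <- build_atlas(peaks)
  atlas <- filter_atlas(atlas, max_width = 3500L)
  # share of input (source) peaks living in fully-overlapping clusters:
  # one row per origin cluster, weighted by its source peak count
  by_cluster <- atlas[!duplicated(atlas$origin_cluster), ]
  case_a_frac <- sum(by_cluster$n_source_peaks[
    by_cluster$merge_case == "A"]) / sum(by_cluster$n_source_peaks)

  log_stage("scan: sequences, thresholds, peak-by-motif matrix")
  pwms <- random_pwms(cfg$n_groups, length = cfg$motif_length,
                      seed = component_seed(cfg$seed, 5L))
  sim_seq <- simulate_sequences(atlas, pwms, cfg)
  thresholds <- lapply(pwms, score_threshold)
  occ <- scan_occurrences(sim_seq$sequences, thresholds)
  groups <- lapply(seq_along(pwms), function(i) {
    list(group_id = pwms[[i]]$name, members = pwms[[i]]$name,
         genes = pwms[[i]]$tf_gene)
  })
  X <- scan_matrix(sim_seq$sequences, groups, thresholds, occurrences = occ)

  log_stage("ridge: svn/svr fits, zeroed-out models, delta-cor")
  sim_acc <- simulate_accessibility(X, cfg)
  y_svn <- stats::setNames(sim_acc$diff$log2fc_svn, sim_acc$diff$feature)
  y_svr <- stats::setNames(sim_acc$diff$log2fc_svr, sim_acc$diff$feature)
  fit_svn <- fit_ridge(X, y_svn, comparison = "svn")
  fit_svr <- fit_ridge(X, y_svr, comparison = "svr")
  zeroed_svn <- zeroed_out_fits(X, y_svn, comparison = "svn")
  paired <- compare_models(fit_svn, fit_svr)
  if (is.null(delta_cor_groups)) {
    delta_cor_groups <- as.integer(names(cfg$planted_betas))
  }
  dc <- lapply(delta_cor_groups, function(g) {
    subset <- which(X[, g] > 0)
    delta_cor(fit_svn, zeroed_svn, subset, y_svn, X,
              subset_label = colnames(X)[g])
  })
  names(dc) <- colnames(X)[delta_cor_groups]
  concord <- shared_fc_concordance(sim_acc$diff, c("svn", "svr"))

  log_stage("integrate: bulk clusters, module scores, enrichment")
  sim_bulk <- simulate_bulk_counts(cfg)
  kept_genes <- filter_genes(sim_bulk$expr)
  de_genes <- intersect(
    kept_genes,
    sim_bulk$diff$feature[!is.na(sim_bulk$diff$padj_svn) &
                            (sim_bulk$diff$padj_svn < 0.05 |
                               sim_bulk$diff$padj_svr < 0.05)])
  km <- kmeans_clusters(sim_bulk$expr, de_genes, k = cfg$k_clusters,
                        seed = component_seed(cfg$seed, 7L))
  cluster_sets <- split(names(km$clusters), km$clusters)
  names(cluster_sets) <- paste0("b", as.roman(as.integer(names(cluster_sets))))
  sim_sc <- simulate_cells(cfg, gene_programs = cluster_sets[
    seq_len(min(3L, length(cluster_sets)))])
  lognorm <- log_normalize_counts(sim_sc$counts)
  scores <- vapply(cluster_sets, function(gs) {
    gs <- intersect(gs, rownames(lognorm))
    if (length(gs) == 0L) return(rep(NA_real_, ncol(lognorm)))
    module_score(lognorm, gs, seed = component_seed(cfg$seed, 13L))
  }, numeric(ncol(lognorm)))
  scores <- scores[, colSums(is.na(scores)) == 0L, drop = FALSE]
  ssm <- subset_score_matrix(scores, sim_sc$cells$subset,
                             min_cells = 20L)

  log_stage("clones: clonotypes, overlap matrices, Mantel")
  sim_tcr <- simulate_clonotypes(cfg)
  clono <- call_clonotypes(sim_tcr$records)
  ovl <- overlap_matrices(clono)
  mantel_pairs <- matrix_reproducibility(
    ovl$per_mouse, seed = component_seed(cfg$seed, 17L))

  results <- list(
    cfg = cfg, atlas = atlas, case_a_frac = case_a_frac,
    sequences = sim_seq, matrix = X, occurrences = occ,
    thresholds = thresholds,
    diff_atac = sim_acc$diff, acc_truth = sim_acc$truth,
    fit_svn = fit_svn, fit_svr = fit_svr, zeroed_svn = zeroed_svn,
    paired = paired, delta_cor = dc, concordance = concord,
    bulk = sim_bulk, gene_clusters = km, cluster_sets = cluster_sets,
    sc = sim_sc, scores = scores, subset_scores = ssm,
    clonotypes = clono, overlap = ovl, mantel_pairs = mantel_pairs)

  if (!is.null(out_dir)) write_pipeline_outputs(results, out_dir)
  results
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

write_pipeline_outputs <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_atlas(results$atlas, file.path(out_dir, "atlas.narrowPeak"))
  write_tsv(data.frame(peak = results$atlas$name,
                       chrom = results$atlas$chrom,
                       start = results$atlas$start,
                       end = results$atlas$end,
                       summit = results$atlas$summit,
                       n_source_peaks = results$atlas$n_source_peaks,
                       merge_case = results$atlas$merge_case),
            file.path(out_dir, "atlas_annot.tsv"))
  mat <- as.data.frame(results$matrix)
  mat <- cbind(peak = rownames(results$matrix), mat)
  write_tsv(mat, file.path(out_dir, "peak_by_motif.tsv"))
  write_tsv(results$paired, file.path(out_dir, "coefficients.tsv"))
  dc_all <- do.call(rbind, lapply(names(results$delta_cor), function(nm) {
    d <- results$delta_cor[[nm]]
    d$subset <- nm
    d
  }))
  write_tsv(dc_all, file.path(out_dir, "deltacor.tsv"))
  write_tsv(data.frame(gene = names(results$gene_clusters$clusters),
                       cluster = results$gene_clusters$clusters),
            file.path(out_dir, "gene_clusters.tsv"))
  write_tsv(results$mantel_pairs, file.path(out_dir, "mantel_pairs.tsv"))
  manifest <- list(
    seed = results$cfg$seed,
    n_atlas_peaks = nrow(results$atlas),
    case_a_frac = results$case_a_frac,
    lambda_svn = results$fit_svn$lambda,
    lambda_svr = results$fit_svr$lambda,
    concordance_r = results$concordance$r,
    stages = c("simulate", "atlas", "scan", "ridge", "integrate",
               "clones"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
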