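# Bulk gene-cluster construction (expression floor, segment exclusion,
# k-means on per-gene Z-scores) and the statistics linking bulk clusters to
# single-cell populations (module scores, subset score matrices,
# hypergeometric enrichment, gene-set shift tests) and to accessibility
# (per-cluster expression-vs-accessibility correlation).

#' Filter genes for bulk clustering
#'
#' Removes genes whose all-sample mean FPKM is below the mean FPKM of a
#' floor gene (default Cd8a, functionally silent in the profiled cells),
#' genes with zero counts in a strict majority of samples, and genes
#' matching immunoglobulin / TCR segment name patterns.
#'
#' @param expr Expression list from [read_expression()].
#' @param floor_gene Floor gene symbol (default "Cd8a").
#' @param segment_patterns Regex vector for segment genes (default: Igh/Igk/
#'   Igl and Tra/Trb/Trg/Trd variable, diversity, joining segments).
#' @return Character vector of retained gene symbols.
#' @export
filter_genes <- function(expr, floor_gene = "Cd8a",
                         segment_patterns = c("^Ig[hkl][vdj]",
                                              "^Tr[abgd][vdj]")) {
  vals <- expr$values
  if (!floor_gene %in% rownames(vals)) {
    stop("floor gene ", floor_gene, " absent from the expression table")
  }
  floor_mean <- mean(vals[floor_gene, ])
  gene_means <- rowMeans(vals)
  n_zero <- rowSums(vals == 0)
  majority_zero <- n_zero > ncol(vals) / 2
  is_segment <- Reduce(`|`, lapply(segment_patterns, function(p) {
    grepl(p, rownames(vals), ignore.case = FALSE)
  }))
  keep <- gene_means >= floor_mean & !majority_zero & !is_segment
  rownames(vals)[keep]
}

#' K-means gene clusters on per-gene Z-scored expression
#'
#' Clusters the differentially expressed genes on per-gene Z-scores with
#' `n_init` random k-means restarts; labels are relabeled deterministically
#' by descending cluster size (ties by first gene).
#'
#' @param expr Expression list.
#' @param genes Genes to cluster (typically DE genes passing
#'   [filter_genes()]).
#' @param k Number of clusters (default 7).
#' @param n_init Random restarts (default 50).
#' @param seed RNG seed.
#' @return List with `clusters` (named integer vector gene -> cluster),
#'   `centroids` (k x samples matrix of mean Z-scores), `zscores`, and the
#'   `kmeans` object.
#' @export
kmeans_clusters <- function(expr, genes, k = 7L, n_init = 50L, seed = 1L) {
  genes <- intersect(genes, rownames(expr$values))
  if (length(genes) < k) stop("fewer genes (", length(genes),
                              ") than clusters (", k, ")")
  z <- t(scale(t(expr$values[genes, , drop = FALSE])))
  z[!is.finite(z)] <- 0  # constant genes carry no profile information
  set.seed(seed)
  if (k == length(genes)) {
    # degenerate limit: every gene is its own cluster, objective 0
    km <- list(cluster = seq_len(k), centers = z,
               tot.withinss = 0, withinss = rep(0, k),
               size = rep(1L, k))
  } else {
    km <- stats::kmeans(z, centers = k, nstart = n_init, iter.max = 100L)
  }
  sizes <- tabulate(km$cluster, k)
  relabel <- order(-sizes, vapply(seq_len(k), function(c) {
    which(km$cluster == c)[1L]
  }, 0L))
  new_label <- match(seq_len(k), relabel)
  clusters <- stats::setNames(new_label[km$cluster], genes)
  centroids <- km$centers[relabel, , drop = FALSE]
  rownames(centroids) <- paste0("b", as.roman(seq_len(k)))
  list(clusters = clusters, centroids = centroids, zscores = z, kmeans = km)
}

log_normalize_counts <- function(counts, scale_factor = 1e4) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  lib[lib == 0] <- 1
  log1p(sweep(counts, 2L, lib, "/") * scale_factor)
}

#' Per-cell module score of a gene set
#'
#' Score = mean log-normalized expression of the set genes minus the mean
#' expression of a pooled control set, where each set gene contributes
#' `n_ctrl` control genes sampled with replacement from its
#' average-expression bin (the binned-control scheme of single-cell module
#' scoring).
#'
#' @param lognorm Log-normalized gene x cell matrix.
#' @param gene_set Character vector of set genes.
#' @param n_bins Number of average-expression bins (default 24).
#' @param n_ctrl Controls drawn per set gene (default 100).
#' @param seed RNG seed for control sampling.
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(lognorm, gene_set, n_bins = 24L, n_ctrl = 100L,
                         seed = 1L) {
  lognorm <- as.matrix(lognorm)
  genes <- intersect(gene_set, rownames(lognorm))
  if (length(genes) == 0L) stop("gene set has no genes in the matrix")
  avg <- rowMeans(lognorm)
  n_bins_eff <- min(n_bins, length(unique(avg)))
  bin <- if (n_bins_eff < 2L) rep(1L, nrow(lognorm)) else
    cut(rank(avg, ties.method = "first"), breaks = n_bins_eff,
        labels = FALSE)
  names(bin) <- rownames(lognorm)
  set.seed(seed)
  ctrl <- unlist(lapply(genes, function(g) {
    pool <- names(bin)[bin == bin[[g]]]
    pool[sample.int(length(pool), n_ctrl, replace = TRUE)]
  }))
  set_score <- colMeans(lognorm[genes, , drop = FALSE])
  ctrl_score <- colMeans(lognorm[ctrl, , drop = FALSE])
  set_score - ctrl_score
}

#' Subset-by-gene-cluster score matrix
#'
#' Computes the mean module score per cell subset (for example cluster x
#' origin), drops subsets with fewer than `min_cells` cells, then
#' Z-normalizes each gene cluster's means across the included subsets.
#' A gene cluster with zero across-subset variance is reported as all
#' zeros with a warning.
#'
#' @param scores Cell x gene-cluster score matrix.
#' @param subsets Character vector of per-cell subset labels.
#' @param min_cells Minimum subset size (default 20).
#' @return List with `z` (subset x gene-cluster Z matrix), `means` (raw
#'   subset means) and `n_cells` per subset.
#' @export
subset_score_matrix <- function(scores, subsets, min_cells = 20L) {
  scores <- as.matrix(scores)
  stopifnot(length(subsets) == nrow(scores))
  counts <- table(subsets)
  keep <- names(counts)[counts >= min_cells]
  if (length(keep) == 0L) stop("no subset reaches ", min_cells, " cells")
  means <- matrix(0, length(keep), ncol(scores),
                  dimnames = list(keep, colnames(scores)))
  for (s in keep) {
    means[s, ] <- colMeans(scores[subsets == s, , drop = FALSE])
  }
  z <- means
  for (j in seq_len(ncol(means))) {
    s <- stats::sd(means[, j])
    if (s == 0 || !is.finite(s)) {
      warning("zero across-subset variance in a gene-cluster score; ",
              "reporting 0")
      z[, j] <- 0
    } else {
      z[, j] <- (means[, j] - mean(means[, j])) / s
    }
  }
  list(z = z, means = means, n_cells = as.integer(counts[keep]))
}

#' Hypergeometric enrichment of a bulk cluster in a single-cell signature
#'
#' Upper-tail probability `P(X >= q)` with `X ~ Hypergeometric(m, n, k)`:
#' `q` genes shared between a bulk cluster and a subset signature, `m`
#' cluster genes, `n` all other detectable genes, `k` signature genes.
#'
#' @param q Overlap count.
#' @param m Bulk cluster gene count.
#' @param n Non-cluster detectable gene count.
#' @param k Signature gene count.
#' @return The enrichment p-value.
#' @export
hypergeom_enrichment <- function(q, m, n, k) {
  stopifnot(q >= 0, m >= 0, n >= 0, k >= 0, k <= m + n)
  if (q > min(m, k)) stop("overlap q exceeds min(m, k)")
  stats::phyper(q - 1, m, n, k, lower.tail = FALSE)
}

#' Distribution shift of a gene set's log2FC (two-sided KS)
#'
#' Two-sample two-sided Kolmogorov-Smirnov test of the set genes' log2FC
#' against a reference. With `background = "all"` the reference is every
#' gene's log2FC (the set included), the figure-legend convention: D is 0
#' when the set is all genes, but the overlap makes null p-values
#' conservative. With `background = "complement"` the reference excludes
#' the set genes; the two samples are disjoint and the null p-value is
#' exactly calibrated.
#'
#' @param fc Named numeric vector of per-gene log2FC.
#' @param gene_set Character vector of set genes.
#' @param background `"all"` (default) or `"complement"`.
#' @return List with `D` statistic, `p` value and set size `n`.
#' @export
geneset_shift_test <- function(fc, gene_set,
                               background = c("all", "complement")) {
  background <- match.arg(background)
  stopifnot(!is.null(names(fc)))
  set_genes <- intersect(gene_set, names(fc))
  set_fc <- fc[set_genes]
  ref <- if (background == "all") fc else
    fc[setdiff(names(fc), set_genes)]
  if (length(set_fc) < 2L || length(ref) < 2L) {
    stop("need at least 2 set genes and 2 background genes")
  }
  kt <- suppressWarnings(stats::ks.test(set_fc, ref,
                                        alternative = "two.sided"))
  list(D = unname(kt$statistic), p = kt$p.value, n = length(set_fc))
}

#' Per-cluster correlation of expression and accessibility fold changes
#'
#' For each gene cluster, pairs every gene's expression log2FC with the
#' log2FC of each atlas peak assigned to that gene (the gene value repeated
#' per peak) and returns the Pearson correlation, per comparison.
#'
#' @param diff_expr Gene differential table (feature = gene).
#' @param diff_atac Peak differential table (feature = peak name).
#' @param links `data.frame` with columns `peak` and `gene` (from the
#'   annotated atlas).
#' @param clusters Named integer vector gene -> cluster.
#' @param comparison Comparison label (matching `log2fc_<comparison>`).
#' @return `data.frame` with `cluster`, `r`, `n_pairs`.
#' @export
cluster_fc_correlation <- function(diff_expr, diff_atac, links, clusters,
                                   comparison = "svn") {
  fc_e <- stats::setNames(diff_expr[[paste0("log2fc_", comparison)]],
                          diff_expr$feature)
  fc_a <- stats::setNames(diff_atac[[paste0("log2fc_", comparison)]],
                          diff_atac$feature)
  links <- links[links$gene %in% names(clusters) &
                   links$gene %in% names(fc_e) &
                   links$peak %in% names(fc_a), , drop = FALSE]
  out <- lapply(sort(unique(clusters)), function(cl) {
    genes_cl <- names(clusters)[clusters == cl]
    lk <- links[links$gene %in% genes_cl, , drop = FALSE]
    if (nrow(lk) < 3L) {
      stop("cluster ", cl, " has fewer than 3 gene-peak pairs")
    }
    data.frame(cluster = cl,
               r = stats::cor(fc_e[lk$gene], fc_a[lk$peak]),
               n_pairs = nrow(lk))
  })
  do.call(rbind, out)
}
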