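# Consensus peak atlas construction.
#
# Per-population peak calls are clustered by single-linkage interval
# overlap (>= 1 bp; bookended half-open intervals do not touch), then each
# cluster is merged: clusters whose summits all fall inside
# [max(starts), min(ends)) collapse to the mean start/summit/end ("full
# overlap"); clusters with summits outside that core are split into one
# peak per distinct summit, bounded by the nearest flanking start/end
# coordinates drawn from any cluster member.

#' Cluster peaks by transitive interval overlap
#'
#' Two peaks share a cluster iff they are connected by a chain of pairwise
#' overlaps of at least 1 bp. Intervals are half-open, so bookended peaks
#' ([100,200) and [200,300)) do not cluster.
#'
#' @param peaks Peak `data.frame` (see [read_narrowpeak()]).
#' @return The peaks with an integer `cluster` column added, sorted by
#'   (chrom, start, end).
#' @export
cluster_peaks <- function(peaks) {
  stopifnot(is.data.frame(peaks))
  if (nrow(peaks) == 0L) {
    peaks$cluster <- integer(0)
    return(peaks)
  }
  ord <- order(peaks$chrom, peaks$start, peaks$end)
  peaks <- peaks[ord, , drop = FALSE]
  n <- nrow(peaks)
  cluster <- integer(n)
  cid <- 0L
  cur_chrom <- ""
  cur_end <- -1L
  for (i in seq_len(n)) {
    # sweep: a sorted peak starts a new cluster unless it overlaps the
    # running maximum end of the current one
    if (peaks$chrom[i] != cur_chrom || peaks$start[i] >= cur_end) {
      cid <- cid + 1L
      cur_chrom <- peaks$chrom[i]
      cur_end <- peaks$end[i]
    } else {
      cur_end <- max(cur_end, peaks$end[i])
    }
    cluster[i] <- cid
  }
  peaks$cluster <- cluster
  rownames(peaks) <- NULL
  peaks
}

round_half_away <- function(x) {
  # round() in R rounds half to even; the atlas uses half away from zero so
  # mean coordinates are order-free and deterministic
  trunc(x + sign(x) * 0.5)
}

#' Merge one peak cluster into atlas peaks
#'
#' Implements the two-case consensus rule. Full-overlap clusters (all
#' summits within `[max(starts), min(ends))`) yield a single peak at the
#' rounded mean start/summit/end. Multi-summit clusters yield one peak per
#' distinct summit coordinate `s`, with boundaries `max{start : start <= s}`
#' and `min{end : end > s}` taken over all cluster members.
#'
#' @param cluster_peaks `data.frame` of peaks from a single cluster.
#' @return `data.frame` of merged peaks with columns `chrom`, `start`,
#'   `end`, `summit`, `score`, `n_source_peaks`, `merge_case` ("A" or "B").
#' @export
merge_cluster <- function(cluster_peaks) {
  n <- nrow(cluster_peaks)
  if (n == 0L) stop("cannot merge an empty cluster")
  chrom <- cluster_peaks$chrom[1L]
  stopifnot(all(cluster_peaks$chrom == chrom))
  starts <- cluster_peaks$start
  ends <- cluster_peaks$end
  summits <- cluster_peaks$summit
  core_lo <- max(starts)
  core_hi <- min(ends)
  full_overlap <- all(summits >= core_lo & summits < core_hi)
  if (full_overlap) {
    start <- round_half_away(mean(starts))
    end <- round_half_away(mean(ends))
    summit <- round_half_away(mean(summits))
    if (start >= end) end <- start + 1L  # guard: rounding collapsed the interval
    summit <- min(max(summit, start), end - 1L)
    return(data.frame(
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      summit = as.integer(summit),
      score = mean(cluster_peaks$score),
      n_source_peaks = n, merge_case = "A", stringsAsFactors = FALSE
    ))
  }
  distinct <- sort(unique(summits))
  out <- lapply(distinct, function(s) {
    lo <- max(starts[starts <= s])
    hi <- min(ends[ends > s])
    data.frame(
      chrom = chrom, start = as.integer(lo), end = as.integer(hi),
      summit = as.integer(s),
      score = mean(cluster_peaks$score[summits == s]),
      n_source_peaks = n, merge_case = "B", stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Build a merged peak atlas from per-population peak calls
#'
#' Concatenates the input peak sets, clusters them by transitive overlap
#' and merges every cluster with [merge_cluster()].
#'
#' @param peak_list List of peak `data.frame`s (one per population), or a
#'   single concatenated `data.frame`.
#' @return Atlas `data.frame` with `name` ("peak_1", ...), `origin_cluster`
#'   and the [merge_cluster()] columns; `category`/`gene` are filled by
#'   [assign_peaks_to_genes()].
#' @export
build_atlas <- function(peak_list) {
  peaks <- if (is.data.frame(peak_list)) peak_list else
    do.call(rbind, peak_list)
  clustered <- cluster_peaks(peaks)
  if (nrow(clustered) == 0L) {
    out <- empty_peaks()
    out$origin_cluster <- integer(0)
    out$n_source_peaks <- integer(0)
    out$merge_case <- character(0)
    return(out)
  }
  merged <- lapply(split(clustered, clustered$cluster), merge_cluster)
  atlas <- do.call(rbind, merged)
  atlas$origin_cluster <- rep.int(
    as.integer(names(merged)), vapply(merged, nrow, 0L))
  atlas <- atlas[order(atlas$chrom, atlas$start, atlas$end), , drop = FALSE]
  atlas$name <- paste0("peak_", seq_len(nrow(atlas)))
  atlas$strand <- "."
  rownames(atlas) <- NULL
  atlas
}

#' Filter an atlas on width, repeat content and chromosome set
#'
#' Retains peaks with width at most `max_width`, repeat fraction at most
#' `repeat_frac` (strictly greater eliminates) and, when `chromosomes` is
#' given, `chrom` in that set. Repeat content comes from soft-masked
#' sequences (fraction of lowercase bases) or a repeat BED (covered
#' fraction); sequences win when both are supplied.
#'
#' @param atlas Atlas `data.frame`.
#' @param max_width Maximum retained peak width in bp (default 3500).
#' @param repeat_frac Maximum retained repeat fraction (default 0.70).
#' @param sequences Optional named character vector or `DNAStringSet`-like
#'   of soft-masked peak sequences, names matching `atlas$name`.
#' @param repeat_bed Optional BED3 `data.frame` of repeat intervals.
#' @param chromosomes Optional character vector of allowed chromosome names.
#' @return The filtered atlas.
#' @export
filter_atlas <- function(atlas, max_width = 3500L, repeat_frac = 0.70,
                         sequences = NULL, repeat_bed = NULL,
                         chromosomes = NULL) {
  keep <- (atlas$end - atlas$start) <= max_width
  if (!is.null(chromosomes)) keep <- keep & atlas$chrom %in% chromosomes
  rf <- repeat_fraction(atlas, sequences, repeat_bed)
  if (!is.null(rf)) keep <- keep & rf <= repeat_frac
  out <- atlas[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

repeat_fraction <- function(atlas, sequences = NULL, repeat_bed = NULL) {
  if (!is.null(sequences)) {
    seqs <- as.character(sequences)
    if (is.null(names(seqs))) names(seqs) <- names(sequences)
    if (is.null(names(seqs))) stop("sequences must be named by peak")
    seqs <- seqs[atlas$name]
    if (anyNA(seqs)) stop("missing sequence for some atlas peaks")
    width <- atlas$end - atlas$start
    if (any(nchar(seqs) != width)) {
      stop("sequence length mismatch with peak width")
    }
    n_lower <- vapply(seqs, function(s) {
      sum(strsplit(s, "")[[1L]] %in% c("a", "c", "g", "t", "n"))
    }, 0L, USE.NAMES = FALSE)
    return(n_lower / width)
  }
  if (!is.null(repeat_bed)) {
    return(vapply(seq_len(nrow(atlas)), function(i) {
      hits <- repeat_bed[repeat_bed$chrom == atlas$chrom[i] &
                           repeat_bed$end > atlas$start[i] &
                           repeat_bed$start < atlas$end[i], , drop = FALSE]
      if (nrow(hits) == 0L) return(0)
      # clip to the peak and merge before summing, so stacked repeat
      # annotations are not double counted
      lo <- pmax(hits$start, atlas$start[i])
      hi <- pmin(hits$end, atlas$end[i])
      ord <- order(lo)
      lo <- lo[ord]; hi <- hi[ord]
      covered <- 0L
      cur_lo <- lo[1L]; cur_hi <- hi[1L]
      for (k in seq_along(lo)[-1L]) {
        if (lo[k] <= cur_hi) cur_hi <- max(cur_hi, hi[k]) else {
          covered <- covered + (cur_hi - cur_lo)
          cur_lo <- lo[k]; cur_hi <- hi[k]
        }
      }
      covered <- covered + (cur_hi - cur_lo)
      covered / (atlas$end[i] - atlas$start[i])
    }, 0))
  }
  NULL
}

#' Assign atlas peaks to their closest genes
#'
#' Category precedence is promoter > intragenic > intergenic > unassigned.
#' A peak is a promoter peak when its summit lies within `promoter_up` bp
#' 5' or `promoter_down` bp 3' of a TSS (strand-aware); an intragenic peak
#' when the summit falls inside a gene body; an intergenic peak when the
#' summit is within `intergenic_window` bp of a gene body. The closest gene
#' is chosen by summit-to-TSS distance for promoter peaks and
#' summit-to-gene-body distance otherwise; ties break lexicographically by
#' gene symbol.
#'
#' @param atlas Atlas `data.frame`.
#' @param genes Gene models from [read_gene_models()].
#' @param promoter_up,promoter_down Promoter window around the TSS in bp
#'   (defaults 2000 upstream and 500 downstream).
#' @param intergenic_window Maximum distance from a gene body for the
#'   intergenic category (default 100000).
#' @return The atlas with `category` and `gene` columns filled.
#' @export
assign_peaks_to_genes <- function(atlas, genes, promoter_up = 2000L,
                                  promoter_down = 500L,
                                  intergenic_window = 100000L) {
  n <- nrow(atlas)
  category <- rep("unassigned", n)
  gene <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    g <- genes[genes$chrom == atlas$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) next
    s <- atlas$summit[i]
    # signed position relative to the TSS in the gene's reading direction:
    # negative = upstream (5'), positive = downstream (3')
    rel <- ifelse(g$strand == "+", s - g$tss, g$tss - s)
    is_prom <- rel >= -promoter_up & rel <= promoter_down
    body_dist <- pmax(g$tx_start - s, s - (g$tx_end - 1L), 0L)
    in_body <- s >= g$tx_start & s < g$tx_end
    if (any(is_prom)) {
      cand <- which(is_prom)
      d <- abs(s - g$tss[cand])
      best <- cand[order(d, g$gene[cand])][1L]
      category[i] <- "promoter"
      gene[i] <- g$gene[best]
    } else if (any(in_body)) {
      cand <- which(in_body)
      d <- abs(s - g$tss[cand])
      best <- cand[order(d, g$gene[cand])][1L]
      category[i] <- "intragenic"
      gene[i] <- g$gene[best]
    } else if (any(body_dist <= intergenic_window)) {
      cand <- which(body_dist <= intergenic_window)
      best <- cand[order(body_dist[cand], g$gene[cand])][1L]
      category[i] <- "intergenic"
      gene[i] <- g$gene[best]
    }
  }
  atlas$category <- category
  atlas$gene <- gene
  atlas
}
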