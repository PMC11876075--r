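# Motif catalog construction: expression filtering, exact score-distribution
# thresholds (FIMO-style P < 1e-4), sequence scanning on both strands,
# enrichment and prevalence filters, and family-constrained motif grouping
# with a gene-uniqueness merge fixpoint.

BASES <- c("A", "C", "G", "T")

#' Keep PWMs whose TF gene is expressed in at least one population
#'
#' A TF passes when its mean FPKM across the samples of any single
#' population is strictly above `floor`.
#'
#' @param pwms List of `pwm` objects.
#' @param expr Expression list from [read_expression()].
#' @param floor FPKM floor (default 1; strict `>`).
#' @return The filtered PWM list. PWMs whose gene is absent from the
#'   expression table are dropped with a warning.
#' @export
filter_expressed <- function(pwms, expr, floor = 1) {
  if (length(pwms) == 0L) return(pwms)
  genes <- vapply(pwms, `[[`, "", "tf_gene")
  known <- genes %in% rownames(expr$values)
  if (any(!known)) {
    warning(sum(!known), " PWM(s) with TF genes absent from the expression",
            " table were dropped: ",
            paste(unique(genes[!known]), collapse = ", "))
  }
  pops <- unique(expr$populations)
  keep <- vapply(seq_along(pwms), function(i) {
    if (!known[i]) return(FALSE)
    v <- expr$values[genes[i], ]
    any(vapply(pops, function(p) {
      mean(v[expr$populations == p]) > floor
    }, FALSE))
  }, FALSE)
  pwms[keep]
}

log_odds_matrix <- function(pwm, background, pseudocount = 1e-4) {
  p <- (pwm$matrix + pseudocount)
  p <- p / rowSums(p)
  sweep(log2(p), 2L, log2(background), "-")
}

#' Exact log-odds score threshold for a PWM
#'
#' Computes the full null score distribution of the PWM under an i.i.d.
#' background by dynamic programming over integerized per-position log-odds
#' scores, and returns the smallest achievable score whose upper-tail
#' probability is at most `pvalue`. When even the maximal score has tail
#' mass above `pvalue` (short or degenerate motifs) the threshold is `Inf`
#' and the motif can match nothing.
#'
#' @param pwm A `pwm` object.
#' @param background Strictly positive base frequencies (A, C, G, T),
#'   summing to 1. Default uniform.
#' @param pvalue Upper-tail probability bound (default 1e-4).
#' @param precision Integerization granularity: number of bins spanning the
#'   widest per-position score range (default 1000).
#' @param pseudocount Probability added to every PWM entry before log-odds
#'   (default 1e-4).
#' @return A `scan_threshold` object: `list(name, background, pvalue,
#'   min_score, min_score_int, int_matrix, scale, offset)`. `min_score` is
#'   on the real log-odds (log2) scale; scanning uses the integer scale for
#'   exact agreement with the DP.
#' @export
score_threshold <- function(pwm, background = rep(0.25, 4), pvalue = 1e-4,
                            precision = 1000L, pseudocount = 1e-4) {
  stopifnot(all(background > 0), abs(sum(background) - 1) < 1e-6,
            pvalue > 0, pvalue < 1)
  S <- log_odds_matrix(pwm, background, pseudocount)
  L <- nrow(S)
  mins <- apply(S, 1L, min)
  ranges <- apply(S, 1L, max) - mins
  scale <- if (max(ranges) > 0) precision / max(ranges) else 1
  int_mat <- round(sweep(S, 1L, mins, "-") * scale)
  storage.mode(int_mat) <- "integer"
  # null distribution over integer scores: convolve position by position
  dist <- 1
  offset0 <- 0L
  for (i in seq_len(L)) {
    width <- max(int_mat[i, ])
    new <- numeric(length(dist) + width)
    for (b in 1:4) {
      sh <- int_mat[i, b]
      idx <- seq_along(dist) + sh
      new[idx] <- new[idx] + dist * background[b]
    }
    dist <- new
  }
  # dist[k] = P(integer score == k - 1)
  tail_p <- rev(cumsum(rev(dist)))
  achievable <- which(dist > 0) - 1L
  ok <- achievable[tail_p[achievable + 1L] <= pvalue]
  if (length(ok) == 0L) {
    min_int <- Inf
    min_real <- Inf
  } else {
    min_int <- min(ok)
    min_real <- min_int / scale + sum(mins)
  }
  structure(list(
    name = pwm$name, background = background, pvalue = pvalue,
    min_score = min_real, min_score_int = min_int,
    int_matrix = int_mat, scale = scale, offset = sum(mins)
  ), class = "scan_threshold")
}

#' @export
print.scan_threshold <- function(x, ...) {
  cat("scan_threshold for", x$name, ": min log-odds score",
      format(x$min_score, digits = 4), "at P <=", x$pvalue, "\n")
  invisible(x)
}

encode_dna <- function(seq) {
  codes <- match(strsplit(toupper(seq), "")[[1L]], BASES)
  codes  # NA for N or other ambiguity codes
}

revcomp_codes <- function(codes) {
  rev(5L - codes)  # A<->T (1<->4), C<->G (2<->3); NA stays NA
}

window_scores_int <- function(codes, int_mat) {
  L <- nrow(int_mat)
  W <- length(codes) - L + 1L
  if (W < 1L) return(integer(0))
  s <- integer(W)
  has_na <- logical(W)
  for (i in seq_len(L)) {
    v <- int_mat[i, ][codes[i:(i + W - 1L)]]
    has_na <- has_na | is.na(v)
    v[is.na(v)] <- 0L
    s <- s + v
  }
  s[has_na] <- NA_integer_  # windows overlapping N are skipped
  s
}

pwm_hits_sequence <- function(codes, threshold) {
  if (!is.finite(threshold$min_score_int)) return(FALSE)
  fwd <- window_scores_int(codes, threshold$int_matrix)
  if (any(!is.na(fwd) & fwd >= threshold$min_score_int)) return(TRUE)
  rev <- window_scores_int(revcomp_codes(codes), threshold$int_matrix)
  any(!is.na(rev) & rev >= threshold$min_score_int)
}

#' Scan sequences for PWM occurrences
#'
#' Both strands are scanned; an entry is 1 when any window meets the PWM's
#' exact-distribution score threshold. Windows overlapping non-ACGT bases
#' are skipped.
#'
#' @param sequences Named character vector (or coercible `DNAStringSet`) of
#'   peak sequences.
#' @param thresholds List of `scan_threshold` objects (one per PWM).
#' @return Binary integer matrix, sequences x PWMs.
#' @export
scan_occurrences <- function(sequences, thresholds) {
  seqs <- as.character(sequences)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  codes_list <- lapply(seqs, encode_dna)
  out <- matrix(0L, nrow = length(seqs), ncol = length(thresholds),
                dimnames = list(names(seqs),
                                vapply(thresholds, `[[`, "", "name")))
  for (j in seq_along(thresholds)) {
    out[, j] <- vapply(codes_list, pwm_hits_sequence, FALSE,
                       threshold = thresholds[[j]])
  }
  out
}

#' Build the binary peak-by-motif-group matrix
#'
#' Entry (peak, group) is 1 iff at least one member PWM of the group has at
#' least one scoring instance in the peak sequence on either strand.
#'
#' @param sequences Named character vector of peak sequences.
#' @param groups List of motif groups (see [group_motifs()]).
#' @param thresholds List of `scan_threshold` objects covering all members.
#' @param occurrences Optional precomputed per-PWM matrix from
#'   [scan_occurrences()] (avoids rescanning).
#' @return Binary integer matrix, peaks x groups.
#' @export
scan_matrix <- function(sequences, groups, thresholds, occurrences = NULL) {
  if (is.null(occurrences)) occurrences <- scan_occurrences(sequences, thresholds)
  out <- matrix(0L, nrow = nrow(occurrences), ncol = length(groups),
                dimnames = list(rownames(occurrences),
                                vapply(groups, `[[`, "", "group_id")))
  for (j in seq_along(groups)) {
    members <- intersect(groups[[j]]$members, colnames(occurrences))
    if (length(members) == 0L) next
    out[, j] <- as.integer(
      rowSums(occurrences[, members, drop = FALSE]) > 0L)
  }
  out
}

#' Enrichment filter against background sequences
#'
#' For every column, a one-sided (greater) Fisher exact test compares the
#' occurrence fraction in the atlas matrix with that in a matched background
#' matrix; Benjamini-Hochberg adjusted p-values below `alpha` are kept.
#'
#' @param matrix Binary occurrence matrix on atlas peaks.
#' @param background_matrix Binary occurrence matrix on background
#'   sequences (same columns).
#' @param alpha Adjusted-p cutoff (default 0.01, strict `<`).
#' @return A `data.frame` with `column`, `p`, `padj`, `keep`.
#' @export
enrichment_filter <- function(matrix, background_matrix, alpha = 0.01) {
  stopifnot(identical(colnames(matrix), colnames(background_matrix)))
  n1 <- nrow(matrix)
  n2 <- nrow(background_matrix)
  p <- vapply(seq_len(ncol(matrix)), function(j) {
    q <- sum(matrix[, j])
    k2 <- sum(background_matrix[, j])
    # one-sided Fisher exact == hypergeometric upper tail at the observed
    # atlas count, drawing n1 from the pooled occurrences
    stats::phyper(q - 1L, q + k2, n1 + n2 - q - k2, n1, lower.tail = FALSE)
  }, 0)
  padj <- stats::p.adjust(p, method = "BH")
  data.frame(column = colnames(matrix), p = p, padj = padj,
             keep = padj < alpha, stringsAsFactors = FALSE)
}

#' Best-offset PWM similarity (E-value-like surrogate)
#'
#' Ungapped Pearson correlation between two probability matrices, maximized
#' over all alignment offsets with at least `min_overlap` overlapping
#' positions and over the reverse-complement orientation. The correlation
#' is mapped onto an E-value-like scale `E = (1 - r) * n_pairs` so that
#' near-duplicate motifs (r -> 1) get E near 0; this surrogate stands in
#' for an external motif-comparison tool and is only meaningful near the
#' duplicate end of the scale.
#'
#' @param pwms List of `pwm` objects.
#' @param min_overlap Minimum aligned columns (default 4).
#' @return `data.frame` with `motif1`, `motif2`, `r`, `evalue`.
#' @export
motif_similarity <- function(pwms, min_overlap = 4L) {
  n <- length(pwms)
  if (n < 2L) {
    return(data.frame(motif1 = character(0), motif2 = character(0),
                      r = numeric(0), evalue = numeric(0)))
  }
  n_pairs <- n * (n - 1L) / 2L
  res <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- best_offset_cor(pwms[[i]]$matrix, pwms[[j]]$matrix, min_overlap)
      res[[length(res) + 1L]] <- data.frame(
        motif1 = pwms[[i]]$name, motif2 = pwms[[j]]$name, r = r,
        evalue = max(1 - r, 0) * n_pairs, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

best_offset_cor <- function(m1, m2, min_overlap = 4L) {
  rc <- function(m) m[rev(seq_len(nrow(m))), 4:1, drop = FALSE]
  best <- -1
  for (m2o in list(m2, rc(m2))) {
    L1 <- nrow(m1); L2 <- nrow(m2o)
    for (off in (-L2 + 1L):(L1 - 1L)) {
      i1 <- max(1L, off + 1L):min(L1, off + L2)
      i2 <- i1 - off
      if (length(i1) < min(min_overlap, L1, L2)) next
      a <- as.vector(m1[i1, , drop = FALSE])
      b <- as.vector(m2o[i2, , drop = FALSE])
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      best <- max(best, stats::cor(a, b))
    }
  }
  best
}

#' Group motifs by similarity within protein families
#'
#' Builds a graph with an edge between two motifs iff their similarity
#' E-value is below `e_cut` and they share a protein family; takes
#' connected components; then repeatedly merges components sharing any TF
#' gene until every gene belongs to at most one group.
#'
#' @param pwms List of `pwm` objects.
#' @param similarity `data.frame` with `motif1`, `motif2`, `evalue`
#'   (precomputed table, or from [motif_similarity()]).
#' @param e_cut E-value cutoff (default 1e-5, strict `<`).
#' @return List of groups: `list(group_id, members, genes)`, ordered by
#'   first member. The groups partition the input PWMs.
#' @export
group_motifs <- function(pwms, similarity = NULL, e_cut = 1e-5) {
  n <- length(pwms)
  if (n == 0L) return(list())
  if (is.null(similarity)) similarity <- motif_similarity(pwms)
  names_ <- vapply(pwms, `[[`, "", "name")
  genes <- vapply(pwms, `[[`, "", "tf_gene")
  families <- vapply(pwms, `[[`, "", "family")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  if (nrow(similarity) > 0L) {
    i1 <- match(similarity$motif1, names_)
    i2 <- match(similarity$motif2, names_)
    for (k in seq_len(nrow(similarity))) {
      a <- i1[k]; b <- i2[k]
      if (is.na(a) || is.na(b)) next
      if (similarity$evalue[k] < e_cut &&
          !is.na(families[a]) && !is.na(families[b]) &&
          families[a] == families[b]) {
        union_(a, b)
      }
    }
  }
  # gene-uniqueness fixpoint: motifs of the same TF gene must share a group
  repeat {
    roots <- vapply(seq_len(n), find, 0L)
    merged_any <- FALSE
    for (g in unique(genes)) {
      idx <- which(genes == g)
      rs <- unique(roots[idx])
      if (length(rs) > 1L) {
        for (r in rs[-1L]) union_(rs[1L], r)
        merged_any <- TRUE
      }
    }
    if (!merged_any) break
  }
  roots <- vapply(seq_len(n), find, 0L)
  comp <- split(seq_len(n), roots)
  comp <- comp[order(vapply(comp, min, 0L))]
  lapply(seq_along(comp), function(k) {
    idx <- sort(comp[[k]])
    list(group_id = paste0("group_", k),
         members = names_[idx],
         genes = sort(unique(genes[idx])))
  })
}

#' Drop motif columns below a prevalence floor
#'
#' @param matrix Binary peak-by-motif matrix.
#' @param min_frac Minimum occurrence fraction (default 0.02; strict `<`
#'   eliminates).
#' @return The matrix restricted to retained columns.
#' @export
prevalence_filter <- function(matrix, min_frac = 0.02) {
  frac <- colMeans(matrix)
  keep <- frac >= min_frac
  if (!any(keep)) {
    stop("all motif columns fall below the prevalence floor (",
         min_frac, "); review the threshold or the scan inputs")
  }
  matrix[, keep, drop = FALSE]
}

#' Pick the representative PWM of a group
#'
#' The member detected in the highest fraction of peaks; ties break
#' lexicographically by motif name.
#'
#' @param group A group from [group_motifs()].
#' @param occurrences Per-PWM binary occurrence matrix
#'   (from [scan_occurrences()]).
#' @return The representative member's name.
#' @export
pick_representative <- function(group, occurrences) {
  members <- intersect(group$members, colnames(occurrences))
  stopifnot(length(members) > 0L)
  frac <- colMeans(occurrences[, members, drop = FALSE])
  members[order(-frac, members)][1L]
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle: generates a uniform random sequence with
#' exactly the same dinucleotide counts as the input, by sampling a random
#' Eulerian path in the dinucleotide transition multigraph.
#'
#' @param seq A single DNA string.
#' @return A shuffled string with identical dinucleotide composition.
#' @export
dinuc_shuffle <- function(seq) {
  chars <- strsplit(seq, "")[[1L]]
  n <- length(chars)
  if (n <= 2L) return(seq)
  verts <- unique(chars)
  last <- chars[n]
  succ <- split(chars[-1L], factor(chars[-n], levels = verts))
  if (length(verts) == 1L) return(seq)
  # choose per-vertex terminal edges forming an arborescence into `last`
  repeat {
    last_edge <- vapply(verts, function(v) {
      if (v == last) return(NA_character_)
      s <- succ[[v]]
      if (length(s) == 0L) return(NA_character_)
      s[sample.int(length(s), 1L)]
    }, "")
    ok <- TRUE
    for (v in verts) {
      if (v == last || is.na(last_edge[[v]])) next
      seen <- character(0)
      cur <- v
      while (cur != last) {
        if (cur %in% seen || is.na(last_edge[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  shuffled <- lapply(verts, function(v) {
    s <- succ[[v]]
    if (is.na(last_edge[[v]]) || v == last) return(sample(s))
    i <- match(last_edge[[v]], s)
    rest <- s[-i]
    c(sample(rest), last_edge[[v]])
  })
  names(shuffled) <- verts
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1L] <- chars[1L]
  cur <- chars[1L]
  for (i in 2:n) {
    nxt <- shuffled[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Build the full motif catalog from PWMs to the peak-by-group matrix
#'
#' Runs the staged filtering pipeline: expression filter, per-PWM
#' enrichment against dinucleotide-shuffled backgrounds, best-PWM-per-gene
#' selection, family-constrained grouping with the gene-uniqueness merge,
#' group-level enrichment prune, group scan, and the prevalence floor.
#'
#' @param pwms List of `pwm` objects.
#' @param sequences Named character vector of atlas peak sequences.
#' @param expr Optional expression list (skips expression filter if NULL).
#' @param similarity Optional precomputed similarity table.
#' @param background 4-vector of base frequencies for thresholds.
#' @param pvalue FIMO-style instance threshold (default 1e-4).
#' @param enrich_alpha Enrichment adjusted-p cutoff (default 0.01).
#' @param e_cut Grouping E-value cutoff (default 1e-5).
#' @param min_frac Prevalence floor (default 0.02).
#' @param expr_floor FPKM floor (default 1).
#' @param seed Seed for the background shuffle.
#' @return List with `matrix` (binary peaks x groups), `groups` (with
#'   representatives), `thresholds`, `occurrences`, and the per-stage
#'   bookkeeping in `stages`.
#' @export
build_motif_catalog <- function(pwms, sequences, expr = NULL,
                                similarity = NULL,
                                background = rep(0.25, 4), pvalue = 1e-4,
                                enrich_alpha = 0.01, e_cut = 1e-5,
                                min_frac = 0.02, expr_floor = 1,
                                seed = 1L) {
  stages <- list(input = vapply(pwms, `[[`, "", "name"))
  if (!is.null(expr)) pwms <- filter_expressed(pwms, expr, floor = expr_floor)
  stages$expressed <- vapply(pwms, `[[`, "", "name")
  if (length(pwms) == 0L) stop("no PWMs pass the expression filter")

  thresholds <- lapply(pwms, score_threshold, background = background,
                       pvalue = pvalue)
  occ <- scan_occurrences(sequences, thresholds)
  withr_seed <- function(expr) { set.seed(seed); expr }
  bg_seqs <- withr_seed(vapply(as.character(sequences), dinuc_shuffle, ""))
  names(bg_seqs) <- paste0("bg_", seq_along(bg_seqs))
  bg_occ <- scan_occurrences(bg_seqs, thresholds)

  enr <- enrichment_filter(occ, bg_occ, alpha = enrich_alpha)
  pwms <- pwms[enr$keep]
  stages$enriched <- vapply(pwms, `[[`, "", "name")
  if (length(pwms) == 0L) stop("no PWMs pass the enrichment filter")

  # best PWM per TF gene: detected in the highest fraction of peaks
  genes <- vapply(pwms, `[[`, "", "tf_gene")
  frac <- colMeans(occ)[vapply(pwms, `[[`, "", "name")]
  best <- unlist(lapply(split(seq_along(pwms), genes), function(idx) {
    nm <- vapply(pwms[idx], `[[`, "", "name")
    idx[order(-frac[nm], nm)][1L]
  }))
  pwms <- pwms[sort(best)]
  stages$best_per_gene <- vapply(pwms, `[[`, "", "name")

  groups <- group_motifs(pwms, similarity = similarity, e_cut = e_cut)

  # group-level enrichment prune
  grp_occ <- scan_matrix(sequences, groups, thresholds,
                         occurrences = occ)
  grp_bg <- scan_matrix(bg_seqs, groups, thresholds,
                        occurrences = bg_occ)
  genr <- enrichment_filter(grp_occ, grp_bg, alpha = enrich_alpha)
  groups <- groups[genr$keep]
  stages$enriched_groups <- vapply(groups, `[[`, "", "group_id")
  if (length(groups) == 0L) stop("no motif groups pass the enrichment prune")

  mat <- scan_matrix(sequences, groups, thresholds, occurrences = occ)
  mat <- prevalence_filter(mat, min_frac = min_frac)
  groups <- groups[vapply(groups, `[[`, "", "group_id") %in% colnames(mat)]
  for (k in seq_along(groups)) {
    groups[[k]]$representative <- pick_representative(groups[[k]], occ)
  }
  stages$final_groups <- vapply(groups, `[[`, "", "group_id")
  list(matrix = mat, groups = groups, thresholds = thresholds,
       occurrences = occ, enrichment = genr, stages = stages)
}
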