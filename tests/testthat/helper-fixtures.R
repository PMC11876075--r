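# Shared fixtures and independent oracles used across the suite.
# Oracles are deliberately naive (brute force / enumeration) and share no
# code path with the implementation they check.

make_peaks <- function(starts, ends, summits = NULL, chrom = "chr1",
                       source = "pop1") {
  n <- length(starts)
  if (is.null(summits)) summits <- (starts + ends) %/% 2L
  data.frame(
    chrom = rep_len(chrom, n), start = as.integer(starts),
    end = as.integer(ends), name = paste0("p", seq_len(n)),
    score = 0, strand = ".", signal = 0, pvalue = -1, qvalue = -1,
    summit = as.integer(summits), source = source,
    stringsAsFactors = FALSE)
}

random_peakset <- function(n, max_pos = 5000L, max_w = 300L) {
  start <- sample.int(max_pos, n, replace = TRUE)
  w <- sample.int(max_w, n, replace = TRUE)
  end <- start + w
  summit <- start + vapply(w, function(x) sample.int(x, 1L) - 1L, 0L)
  make_peaks(start, end, summit,
             chrom = sample(c("chr1", "chr2"), n, replace = TRUE))
}

# O(n^2) single-linkage overlap clustering: adjacency + BFS components
oracle_clusters <- function(peaks) {
  n <- nrow(peaks)
  same <- outer(peaks$chrom, peaks$chrom, "==")
  ov <- outer(peaks$start, peaks$end, "<") &
    t(outer(peaks$start, peaks$end, "<")) & same
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cid <- cid + 1L
    queue <- i
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      if (comp[v] > 0L) next
      comp[v] <- cid
      queue <- c(queue, which(ov[v, ] & comp == 0L))
    }
  }
  comp
}

# exhaustive 4^L word enumeration: the smallest achievable integer score
# whose exact null upper-tail mass is <= pvalue (Inf when none)
oracle_threshold_int <- function(int_mat, background, pvalue) {
  L <- nrow(int_mat)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- integer(nrow(words))
  pr <- rep(1, nrow(words))
  for (i in seq_len(L)) {
    sc <- sc + int_mat[i, words[, i]]
    pr <- pr * background[words[, i]]
  }
  agg <- tapply(pr, sc, sum)
  scores <- as.integer(names(agg))
  o <- order(scores)
  scores <- scores[o]
  tail_mass <- rev(cumsum(rev(agg[o])))
  ok <- scores[tail_mass <= pvalue]
  if (length(ok) == 0L) Inf else min(ok)
}

# direct combinatorial hypergeometric upper tail P(X >= q)
oracle_hyper_tail <- function(q, m, n, k) {
  xs <- max(q, max(0L, k - n)):min(m, k)
  if (q > min(m, k)) stop("invalid q")
  sum(choose(m, xs) * choose(n, k - xs)) / choose(m + n, k)
}

new_pwm_for_tests <- function(name, tf_gene = name, family = "fam1",
                              L = 6L) {
  structure(list(
    name = name, tf_gene = tf_gene, family = family,
    matrix = matrix(0.25, L, 4L,
                    dimnames = list(NULL, c("A", "C", "G", "T")))),
    class = "pwm")
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  }, "")
}

dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1L]]
  if (length(ch) < 2L) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1L]))
}

# agreement of two labelings after the best one-to-one label matching
# (exhaustive over label permutations; fine for k <= 7)
matched_agreement <- function(truth, est) {
  k <- max(truth, est)
  perms <- ridgemotif_all_perms(k)
  best <- 0
  for (p in perms) best <- max(best, mean(p[est] == truth))
  best
}

ridgemotif_all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- ridgemotif_all_perms(n - 1L)
  out <- list()
  for (i in seq_len(n)) {
    for (s in sub) {
      v <- integer(n); v[i] <- n; v[-i] <- s
      out[[length(out) + 1L]] <- v
    }
  }
  out
}
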