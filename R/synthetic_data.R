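# Deterministic synthetic-data generator with planted ground truth for
# every pipeline stage: replicate peak calls around latent loci, peak
# sequences with planted motif instances, per-peak log2FC as a linear
# function of motif presence plus Gaussian noise, negative-binomial bulk
# counts under a 3-population x 3-replicate design with 7 planted gene
# archetypes, cell-by-gene matrices with program structure, and clonotype
# tables matching a planted phenotype-overlap matrix.
#
# One global seed fans out to per-component streams (seed * 97 + a fixed
# component offset, kept below 2^31), so adding a component does not
# perturb the draws of the others.

#' Simulation configuration
#'
#' Defaults encode the study design the generator emulates: 3 cell
#' populations x 3 replicates, 7 bulk gene archetypes, 3 planted motif
#' effects among `n_groups` motif groups, and a planted clonal-overlap
#' matrix across phenotypes and mice.
#'
#' @param seed Global seed; all component streams derive from it.
#' @param n_loci Latent accessible loci (atlas peaks before filtering).
#' @param multi_summit_frac Fraction of loci emitting two-summit clusters.
#'   The default 0.10 makes ~82% of all emitted source peaks fall in
#'   fully-overlapping clusters, the share reported for the emulated
#'   study design.
#' @param n_populations,n_replicates Peak-call design (defaults 3 x 3).
#' @param peak_width Nominal peak width in bp.
#' @param jitter_sd SD of replicate boundary/summit jitter in bp.
#' @param n_groups Motif groups (default 40).
#' @param motif_length PWM length (default 8).
#' @param placement_prob Per-(peak, group) probability of planting one
#'   motif instance (default 0.3).
#' @param planted_betas Named (by group index) effect vector; default
#'   groups 1-3 at +0.8, +0.5, -0.8 and 0 elsewhere.
#' @param noise_sd Gaussian noise SD on per-peak log2FC (default 0.5).
#' @param n_genes Bulk genes (default 700).
#' @param k_clusters Planted gene archetypes (default 7).
#' @param nb_dispersion Negative-binomial dispersion (default 0.3).
#' @param n_cells Cells in the single-cell matrix (default 600).
#' @param program_effect Multiplicative program overexpression (default 4).
#' @param n_mice Mice for clonotype tables (default 3).
#' @param n_clones Clones per phenotype per mouse (default 150).
#' @param clonal_overlap_target Symmetric matrix in `[0,1]` with unit
#'   diagonal; default 4 phenotypes with one strong (0.5), one moderate
#'   (0.2) and weak (0.05) remaining overlaps.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_loci = 300L, multi_summit_frac = 0.10,
                       n_populations = 3L, n_replicates = 3L,
                       peak_width = 400L, jitter_sd = 15,
                       n_groups = 40L, motif_length = 8L,
                       placement_prob = 0.3,
                       planted_betas = c(`1` = 0.8, `2` = 0.5, `3` = -0.8),
                       noise_sd = 0.5,
                       n_genes = 700L, k_clusters = 7L, nb_dispersion = 0.3,
                       n_cells = 600L, program_effect = 4,
                       n_mice = 3L, n_clones = 150L,
                       clonal_overlap_target = NULL) {
  if (is.null(clonal_overlap_target)) {
    clonal_overlap_target <- matrix(0.05, 4, 4)
    clonal_overlap_target[1, 2] <- clonal_overlap_target[2, 1] <- 0.5
    clonal_overlap_target[3, 4] <- clonal_overlap_target[4, 3] <- 0.2
    diag(clonal_overlap_target) <- 1
    dimnames(clonal_overlap_target) <- list(paste0("ph", 1:4),
                                            paste0("ph", 1:4))
  }
  validate_overlap_target(clonal_overlap_target)
  stopifnot(n_loci >= 0, n_populations >= 1, n_replicates >= 1,
            noise_sd >= 0, nb_dispersion >= 0, multi_summit_frac >= 0,
            multi_summit_frac <= 1, placement_prob >= 0,
            placement_prob <= 1)
  structure(list(
    seed = as.integer(seed), n_loci = n_loci,
    multi_summit_frac = multi_summit_frac,
    n_populations = n_populations, n_replicates = n_replicates,
    peak_width = peak_width, jitter_sd = jitter_sd,
    n_groups = n_groups, motif_length = motif_length,
    placement_prob = placement_prob, planted_betas = planted_betas,
    noise_sd = noise_sd, n_genes = n_genes, k_clusters = k_clusters,
    nb_dispersion = nb_dispersion, n_cells = n_cells,
    program_effect = program_effect, n_mice = n_mice,
    n_clones = n_clones, clonal_overlap_target = clonal_overlap_target
  ), class = "sim_config")
}

validate_overlap_target <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (any(abs(m - t(m)) > 1e-12)) stop("overlap target must be symmetric")
  if (any(m < 0 | m > 1)) stop("overlap target entries must be in [0, 1]")
  if (any(diag(m) != 1)) stop("overlap target diagonal must be 1")
  off <- m; diag(off) <- 0
  if (any(off >= 1)) stop("infeasible target: off-diagonal >= diagonal")
  invisible(m)
}

component_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + offset) %% 2147483629)
}

#' Simulate per-population replicate peak calls
#'
#' Latent loci are laid along one chromosome; each population's call jitters
#' the locus boundaries and summit. A configured fraction of loci emit two
#' offset sub-peaks with distinct summits, producing multi-summit clusters
#' for the split rule.
#'
#' @param cfg A [sim_config()].
#' @return List with `peaks` (list of per-population peak `data.frame`s)
#'   and `truth` (locus table with the planted merge case).
#' @export
simulate_peak_calls <- function(cfg) {
  set.seed(component_seed(cfg$seed, 11L))
  n <- cfg$n_loci
  if (n == 0L) {
    return(list(peaks = replicate(cfg$n_populations, empty_peaks(),
                                  simplify = FALSE),
                truth = data.frame(locus = integer(0), start = integer(0),
                                   multi_summit = logical(0))))
  }
  gap <- cfg$peak_width * 3L + 1000L
  locus_start <- 1000L + (seq_len(n) - 1L) * gap
  multi <- stats::runif(n) < cfg$multi_summit_frac
  pops <- paste0("pop", seq_len(cfg$n_populations))
  jit <- function(k) as.integer(round(stats::rnorm(k, 0, cfg$jitter_sd)))
  peaks <- lapply(pops, function(pop) {
    rows <- list()
    for (i in seq_len(n)) {
      w <- cfg$peak_width
      if (multi[i]) {
        # two offset sub-peaks sharing >= 1 bp: distinct summits fall
        # outside the cluster core, forcing the split rule
        s1 <- locus_start[i] + jit(1L)
        p1 <- c(s1, s1 + w)
        s2 <- locus_start[i] + as.integer(w * 0.8) + jit(1L)
        p2 <- c(s2, s2 + w)
        sm1 <- s1 + as.integer(w * 0.3)
        sm2 <- s2 + as.integer(w * 0.7)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = "chr1", start = c(p1[1L], p2[1L]),
          end = c(p1[2L], p2[2L]),
          summit = c(sm1, sm2), locus = i, stringsAsFactors = FALSE)
      } else {
        a <- locus_start[i] + jit(1L)
        b <- a + w + jit(1L)
        sm <- a + as.integer(w / 2) + jit(1L)
        sm <- min(max(sm, a), b - 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = "chr1", start = a, end = b, summit = sm, locus = i,
          stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    data.frame(
      chrom = df$chrom, start = df$start, end = df$end,
      name = paste0(pop, "_peak_", seq_len(nrow(df))),
      score = 100, strand = ".", signal = 5, pvalue = -1, qvalue = -1,
      summit = df$summit, source = pop, locus = df$locus,
      stringsAsFactors = FALSE)
  })
  names(peaks) <- pops
  list(peaks = peaks,
       truth = data.frame(locus = seq_len(n), start = locus_start,
                          multi_summit = multi))
}

#' Generate sharp random PWMs for the simulator
#'
#' Consensus-dominated PWMs (consensus base probability `sharpness`) with
#' random consensus words, one per motif group.
#'
#' @param n Number of PWMs.
#' @param length Motif length.
#' @param seed RNG seed.
#' @param sharpness Consensus base probability (default 0.91).
#' @param family Family label applied to all (default "simfam").
#' @return List of `pwm` objects named `motif_1..n` with
#'   `tf_gene = Tf1..n`.
#' @export
random_pwms <- function(n, length = 8L, seed = 1L, sharpness = 0.91,
                        family = "simfam") {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    cons <- sample.int(4L, length, replace = TRUE)
    mat <- matrix((1 - sharpness) / 3, length, 4L)
    mat[cbind(seq_len(length), cons)] <- sharpness
    new_pwm(paste0("motif_", i), mat, tf_gene = paste0("Tf", i),
            family = family)
  })
}

consensus_word <- function(pwm) {
  paste(BASES[apply(pwm$matrix, 1L, which.max)], collapse = "")
}

#' Simulate peak sequences with planted motif instances
#'
#' Background bases are drawn i.i.d. from `base_freq`; for each
#' (peak, group) the PWM's consensus word is planted with probability
#' `placement_prob`, at a uniform offset on either strand. Planting the
#' consensus (rather than a per-position sample) makes the planted binary
#' occupancy exact under the exact-distribution scan threshold, which is
#' what a designed ground-truth matrix requires.
#'
#' @param atlas Atlas `data.frame` (uses `name` and widths).
#' @param pwms List of `pwm` objects (one representative per group).
#' @param cfg A [sim_config()]; `placement_prob` may be a scalar or a
#'   per-group vector.
#' @param base_freq Background base frequencies (default uniform).
#' @return List with `sequences` (named character vector) and `placements`
#'   (`data.frame` peak/group/offset/strand).
#' @export
simulate_sequences <- function(atlas, pwms, cfg,
                               base_freq = rep(0.25, 4)) {
  set.seed(component_seed(cfg$seed, 23L))
  widths <- atlas$end - atlas$start
  prob <- rep(cfg$placement_prob, length.out = length(pwms))
  seqs <- vapply(widths, function(w) {
    paste(sample(BASES, w, replace = TRUE, prob = base_freq),
          collapse = "")
  }, "")
  names(seqs) <- atlas$name
  placements <- list()
  occupied <- vector("list", length(seqs))  # planted intervals per peak
  for (j in seq_along(pwms)) {
    L <- nrow(pwms[[j]]$matrix)
    if (any(widths < L)) stop("motif longer than a peak sequence")
    plant <- stats::runif(length(seqs)) < prob[j]
    for (i in which(plant)) {
      word <- consensus_word(pwms[[j]])
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") word <- revcomp_string(word)
      # avoid overwriting an earlier group's instance (rejection sampling;
      # falls back to an overlapping offset only if space runs out)
      off <- sample.int(widths[i] - L + 1L, 1L)
      for (try in seq_len(50L)) {
        clash <- any(vapply(occupied[[i]], function(iv) {
          off <= iv[2L] && iv[1L] <= off + L - 1L
        }, FALSE))
        if (!clash) break
        off <- sample.int(widths[i] - L + 1L, 1L)
      }
      occupied[[i]] <- c(occupied[[i]], list(c(off, off + L - 1L)))
      substr(seqs[i], off, off + L - 1L) <- word
      placements[[length(placements) + 1L]] <- data.frame(
        peak = atlas$name[i], group = pwms[[j]]$name, offset = off,
        strand = strand, stringsAsFactors = FALSE)
    }
  }
  placements <- if (length(placements) > 0L) do.call(rbind, placements) else
    data.frame(peak = character(0), group = character(0),
               offset = integer(0), strand = character(0))
  list(sequences = seqs, placements = placements)
}

revcomp_string <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Simulate differential accessibility from motif presence
#'
#' `y = X beta + N(0, noise_sd^2)` per comparison. Adjusted p-values are a
#' rank-based stand-in: peaks in the top `de_frac` by `|y|` get
#' `padj ~ U(0, 0.05)`, the rest `U(0.05, 1)`.
#'
#' @param X Binary peak-by-motif-group matrix.
#' @param cfg A [sim_config()].
#' @param beta_svn,beta_svr Full-length effect vectors; default expands
#'   `cfg$planted_betas` (same vector for both comparisons).
#' @param de_frac Fraction of peaks flagged differential (default 0.25).
#' @return List with `diff` (feature/log2fc/padj table) and `truth`
#'   (beta vectors and noiseless signals).
#' @export
simulate_accessibility <- function(X, cfg, beta_svn = NULL, beta_svr = NULL,
                                   de_frac = 0.25) {
  set.seed(component_seed(cfg$seed, 37L))
  X <- as.matrix(X)
  expand <- function(b) {
    out <- numeric(ncol(X))
    if (!is.null(names(b))) {
      out[as.integer(names(b))] <- b
    } else {
      out[seq_along(b)] <- b
    }
    out
  }
  if (is.null(beta_svn)) beta_svn <- expand(cfg$planted_betas)
  if (is.null(beta_svr)) beta_svr <- expand(cfg$planted_betas)
  stopifnot(length(beta_svn) == ncol(X), length(beta_svr) == ncol(X))
  n <- nrow(X)
  sig_svn <- drop(X %*% beta_svn)
  sig_svr <- drop(X %*% beta_svr)
  y_svn <- sig_svn + stats::rnorm(n, 0, cfg$noise_sd)
  y_svr <- sig_svr + stats::rnorm(n, 0, cfg$noise_sd)
  padj_of <- function(y) {
    top <- rank(-abs(y), ties.method = "first") <= ceiling(de_frac * n)
    p <- numeric(n)
    p[top] <- stats::runif(sum(top), 0, 0.05)
    p[!top] <- stats::runif(sum(!top), 0.05, 1)
    p
  }
  diff <- data.frame(
    feature = rownames(X), log2fc_svn = y_svn, log2fc_svr = y_svr,
    padj_svn = padj_of(y_svn), padj_svr = padj_of(y_svr),
    stringsAsFactors = FALSE)
  attr(diff, "comparisons") <- c("svn", "svr")
  list(diff = diff,
       truth = list(beta_svn = beta_svn, beta_svr = beta_svr,
                    signal_svn = sig_svn, signal_svr = sig_svr))
}

archetype_patterns <- function(k) {
  # population-mean log2 offsets (neg, recent, stable). After per-gene
  # Z-scoring a 3-point profile is identified only by its direction in the
  # centered plane, so the k archetypes are k equally spaced directions in
  # that plane; direction 1 is the monotone-up (bIV-like) profile and the
  # opposite one monotone-down (bI-like).
  u1 <- c(-1, 0, 1) / sqrt(2)
  u2 <- c(1, -2, 1) / sqrt(6)
  theta <- 2 * pi * (seq_len(k) - 1L) / k
  t(vapply(theta, function(a) cos(a) * u1 + sin(a) * u2, numeric(3L)))
}

#' Simulate bulk expression under the 3-population design
#'
#' Negative-binomial counts for `n_genes` genes across populations x
#' replicates, with `k_clusters` planted archetype patterns on a subset of
#' genes, a planted low-expression floor gene ("Cd8a"), genes planted below
#' the floor, and Ig/TCR segment-named genes. FPKM-like values are
#' library-size normalized counts.
#'
#' @param cfg A [sim_config()].
#' @param effect_size Log2 amplitude of the archetype patterns (default 2).
#' @param frac_de Fraction of genes given an archetype (default 0.5).
#' @return List with `expr` (as from [read_expression()]), `diff` (gene
#'   differential table, svn/svr), and `truth` (archetype labels).
#' @export
simulate_bulk_counts <- function(cfg, effect_size = 2, frac_de = 0.5) {
  set.seed(component_seed(cfg$seed, 53L))
  n_genes <- cfg$n_genes
  k <- cfg$k_clusters
  pops <- c("neg", "recent", "stable")[seq_len(min(3L, cfg$n_populations))]
  if (cfg$n_populations > 3L) {
    pops <- c(pops, paste0("pop", 4:cfg$n_populations))
  }
  samples <- as.vector(outer(pops, seq_len(cfg$n_replicates),
                             function(p, r) paste0(p, "_r", r)))
  populations <- stats::setNames(rep(pops, cfg$n_replicates), samples)

  n_de <- ceiling(frac_de * n_genes)
  archetype <- rep(0L, n_genes)
  archetype[seq_len(n_de)] <- rep_len(seq_len(k), n_de)
  patterns <- archetype_patterns(k)

  base_log2 <- stats::runif(n_genes, 3, 9)
  genes <- paste0("Gene", seq_len(n_genes))
  # planted special genes at the tail: floor gene, sub-floor genes,
  # segment-named genes (all non-DE)
  floor_idx <- n_genes
  genes[floor_idx] <- "Cd8a"
  base_log2[floor_idx] <- 2
  archetype[floor_idx] <- 0L
  sub_floor <- (n_genes - 20L):(n_genes - 11L)
  genes[sub_floor] <- paste0("LowGene", seq_along(sub_floor))
  base_log2[sub_floor] <- 0.3
  archetype[sub_floor] <- 0L
  seg <- (n_genes - 10L):(n_genes - 1L)
  genes[seg] <- c(paste0("Ighv", 1:3), paste0("Trbv", 1:3),
                  paste0("Trav", 1:2), "Igkj1", "Trbj2")
  archetype[seg] <- 0L

  mu <- matrix(0, n_genes, length(samples),
               dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    pop_i <- match(populations[j], pops)
    off <- ifelse(archetype > 0L & pop_i <= 3L,
                  patterns[pmax(archetype, 1L), pop_i] * effect_size / 2,
                  0)
    mu[, j] <- 2^(base_log2 + off)
  }
  size <- if (cfg$nb_dispersion > 0) 1 / cfg$nb_dispersion else Inf
  counts <- matrix(
    if (is.finite(size)) {
      stats::rnbinom(length(mu), mu = as.vector(mu), size = size)
    } else {
      stats::rpois(length(mu), as.vector(mu))
    },
    n_genes, length(samples), dimnames = dimnames(mu))
  lib <- colSums(counts)
  fpkm <- sweep(counts, 2L, lib, "/") * 1e6  # unit gene length
  expr <- list(values = fpkm, genes = genes, samples = samples,
               populations = populations)

  mean_pop <- function(p) rowMeans(fpkm[, populations == p, drop = FALSE])
  eps <- 0.5
  lfc_svn <- log2((mean_pop("stable") + eps) / (mean_pop("neg") + eps))
  lfc_svr <- log2((mean_pop("stable") + eps) / (mean_pop("recent") + eps))
  padj_of <- function(lfc) {
    top <- rank(-abs(lfc), ties.method = "first") <= n_de
    p <- numeric(n_genes)
    p[top] <- stats::runif(sum(top), 0, 0.05)
    p[!top] <- stats::runif(sum(!top), 0.05, 1)
    p
  }
  diff <- data.frame(feature = genes, log2fc_svn = lfc_svn,
                     log2fc_svr = lfc_svr, padj_svn = padj_of(lfc_svn),
                     padj_svr = padj_of(lfc_svr), stringsAsFactors = FALSE)
  attr(diff, "comparisons") <- c("svn", "svr")
  list(expr = expr, diff = diff,
       truth = list(archetype = stats::setNames(archetype, genes),
                    patterns = patterns))
}

#' Simulate a cell-by-gene count matrix with program structure
#'
#' Cells are assigned to programs aligned with planted bulk gene clusters;
#' a program's cells overexpress that cluster's genes by
#' `cfg$program_effect`. Counts are Poisson draws on log-normal rates.
#' Cells also carry an origin label (tdTomato-like two-level factor).
#'
#' @param cfg A [sim_config()].
#' @param gene_programs Named list program -> gene set (for example planted
#'   bulk clusters); default: programs over slices of `Gene1..n`.
#' @param n_programs Number of programs when `gene_programs` is NULL.
#' @return List with `counts` (sparse genes x cells), `cells`
#'   (`data.frame` cell_id, program, origin, subset) and `truth`.
#' @export
simulate_cells <- function(cfg, gene_programs = NULL, n_programs = 3L) {
  set.seed(component_seed(cfg$seed, 71L))
  if (is.null(gene_programs)) {
    per <- 40L
    gene_programs <- lapply(seq_len(n_programs), function(p) {
      paste0("Gene", ((p - 1L) * per + 1L):(p * per))
    })
    names(gene_programs) <- paste0("prog", seq_len(n_programs))
  }
  n_programs <- length(gene_programs)
  all_genes <- unique(c(unlist(gene_programs),
                        paste0("Gene", seq_len(max(200L, cfg$n_genes %/% 2L)))))
  n_cells <- cfg$n_cells
  program <- sample(names(gene_programs), n_cells, replace = TRUE)
  origin <- sample(c("tdTomato_pos", "tdTomato_neg"), n_cells,
                   replace = TRUE)
  base_rate <- stats::rlnorm(length(all_genes), meanlog = 0, sdlog = 1)
  names(base_rate) <- all_genes
  rate <- matrix(base_rate, length(all_genes), n_cells,
                 dimnames = list(all_genes, paste0("cell_", seq_len(n_cells))))
  for (p in names(gene_programs)) {
    idx <- all_genes %in% gene_programs[[p]]
    rate[idx, program == p] <- rate[idx, program == p] * cfg$program_effect
  }
  counts <- matrix(stats::rpois(length(rate), as.vector(rate)),
                   nrow(rate), ncol(rate), dimnames = dimnames(rate))
  cells <- data.frame(
    cell_id = colnames(counts), program = program, origin = origin,
    subset = paste(program, origin, sep = "."), stringsAsFactors = FALSE)
  list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                            "CsparseMatrix"),
       cells = cells,
       truth = list(programs = gene_programs))
}

#' Simulate clonotype tables matching a planted overlap matrix
#'
#' Per mouse, each phenotype holds `n_clones` clonotypes. For every
#' phenotype pair with target Jaccard `J`, `s = round(J * 2C / (1 + J))`
#' clones are shared (members of exactly that pair), the rest private, so
#' the realized pairwise Jaccard matches the target by construction.
#' Clones beyond pairwise sharing are not modeled. Each clone emits 1-3
#' cells per member phenotype with unique random TRA/TRB CDR3 strings per
#' clone.
#'
#' @param cfg A [sim_config()]; uses `clonal_overlap_target`, `n_clones`,
#'   `n_mice`.
#' @return List with `records` (chain-level `data.frame` readable by the
#'   clonotype pipeline) and `truth` (the target matrix).
#' @export
simulate_clonotypes <- function(cfg) {
  set.seed(component_seed(cfg$seed, 89L))
  target <- cfg$clonal_overlap_target
  validate_overlap_target(target)
  phenos <- rownames(target)
  K <- length(phenos)
  C <- cfg$n_clones
  shared <- matrix(0L, K, K, dimnames = dimnames(target))
  for (i in seq_len(K - 1L)) {
    for (j in (i + 1L):K) {
      shared[i, j] <- shared[j, i] <-
        as.integer(round(target[i, j] * 2 * C / (1 + target[i, j])))
    }
  }
  if (any(rowSums(shared) > C)) {
    stop("infeasible overlap target: shared clones exceed phenotype size")
  }
  rand_cdr3 <- function(n, len = 30L) {
    vapply(seq_len(n), function(i) {
      paste(sample(BASES, len, replace = TRUE), collapse = "")
    }, "")
  }
  records <- list()
  clone_counter <- 0L
  for (m in seq_len(cfg$n_mice)) {
    mouse <- paste0("mouse", m)
    memberships <- list()
    for (i in seq_len(K - 1L)) {
      for (j in (i + 1L):K) {
        if (shared[i, j] > 0L) {
          memberships <- c(memberships, rep(
            list(c(phenos[i], phenos[j])), shared[i, j]))
        }
      }
    }
    for (i in seq_len(K)) {
      n_priv <- C - sum(shared[i, ])
      memberships <- c(memberships, rep(list(phenos[i]), n_priv))
    }
    n_cl <- length(memberships)
    tra <- rand_cdr3(n_cl)
    trb <- rand_cdr3(n_cl)
    for (ci in seq_len(n_cl)) {
      clone_counter <- clone_counter + 1L
      for (ph in memberships[[ci]]) {
        n_cells <- sample.int(3L, 1L)
        for (cc in seq_len(n_cells)) {
          cell <- sprintf("%s_c%07d_%s_%d", mouse, clone_counter, ph, cc)
          records[[length(records) + 1L]] <- data.frame(
            cell_id = cell, mouse_id = mouse, phenotype = ph,
            chain = c("TRA", "TRB"), cdr3_nt = c(tra[ci], trb[ci]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(records = do.call(rbind, records), truth = list(target = target))
}
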