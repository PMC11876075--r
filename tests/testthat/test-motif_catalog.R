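make_expr <- function(means_by_pop, gene = "Tf1") {
  # 3 populations x 2 replicates with exact per-population means
  vals <- matrix(rep(unlist(means_by_pop), each = 2L), nrow = 1L)
  samples <- as.vector(outer(c("r1", "r2"), names(means_by_pop),
                             function(r, p) paste0(p, "_", r)))
  vals <- matrix(rep(unlist(means_by_pop), each = 2L), nrow = 1L,
                 dimnames = list(gene, samples))
  list(values = vals, genes = gene, samples = samples,
       populations = stats::setNames(rep(names(means_by_pop), each = 2L),
                                     samples))
}

test_that("expression filter keeps TFs above the floor in any population", {
  pwm <- random_pwms(1L, seed = 1L)[[1L]]
  expr <- make_expr(c(neg = 0.5, recent = 1.2, stable = 0.3))
  expect_length(filter_expressed(list(pwm), expr), 1L)

  expr2 <- make_expr(c(neg = 1.0, recent = 1.0, stable = 1.0))
  expect_length(filter_expressed(list(pwm), expr2), 0L)  # strict >

  expect_length(filter_expressed(list(), expr), 0L)

  stranger <- new_pwm_for_tests("mX", tf_gene = "NotAGene")
  expect_warning(out <- filter_expressed(list(stranger), expr), "absent")
  expect_length(out, 0L)
})

test_that("degenerate PWMs yield the infinite threshold sentinel", {
  # one-position motif: even the best base has null mass 0.25 > 1e-4
  m <- matrix(c(1, 0, 0, 0), 1L, 4L)
  p1 <- structure(list(name = "m1", tf_gene = "m1", family = NA,
                       matrix = m), class = "pwm")
  th <- score_threshold(p1)
  expect_identical(th$min_score, Inf)

  # uniform motif: all words score 0, tail mass 1
  pu <- structure(list(name = "mu", tf_gene = "mu", family = NA,
                       matrix = matrix(0.25, 6L, 4L)), class = "pwm")
  thu <- score_threshold(pu)
  expect_identical(thu$min_score, Inf)
})

test_that("thresholds equal exhaustive word enumeration for short motifs", {
  set.seed(11)
  for (rep in 1:6) {
    L <- sample(4:8, 1L)
    pwm <- random_pwms(1L, length = L, seed = rep,
                       sharpness = runif(1, 0.5, 0.95))[[1L]]
    bg <- as.vector(stats::rgamma(4, 5)); bg <- bg / sum(bg)
    th <- score_threshold(pwm, background = bg)
    expect_equal(th$min_score_int,
                 oracle_threshold_int(th$int_matrix, bg, th$pvalue))
  }
})

test_that("scanning finds planted instances on both strands and skips Ns", {
  pwm <- random_pwms(1L, length = 8L, seed = 3L, sharpness = 0.97)[[1L]]
  cons <- paste(c("A", "C", "G", "T")[apply(pwm$matrix, 1, which.max)],
                collapse = "")
  th <- list(score_threshold(pwm))
  set.seed(5)
  bgs <- random_dna(3L, 60L)
  planted <- paste0(substr(bgs[1L], 1L, 10L), cons,
                    substr(bgs[1L], 19L, 60L))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cons)))
  planted_rc <- paste0(substr(bgs[2L], 1L, 10L), rc,
                       substr(bgs[2L], 19L, 60L))
  seqs <- c(fwd = planted, rev = planted_rc, none = bgs[3L])
  occ <- scan_occurrences(seqs, th)
  expect_equal(unname(occ[, 1L]), c(1L, 1L, 0L))

  # strand symmetry: the reverse complement of every sequence scans equal
  seqs_rc <- vapply(seqs, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, "")
  expect_equal(unname(scan_occurrences(seqs_rc, th)[, 1L]),
               unname(occ[, 1L]))

  # N bases void the windows that overlap them
  masked <- paste0(substr(planted, 1L, 13L), "N", substr(planted, 15L, 60L))
  expect_equal(unname(scan_occurrences(c(m = masked), th)[, 1L]), 0L)
})

test_that("uniform motifs match nothing in random sequence", {
  pu <- structure(list(name = "mu", tf_gene = "mu", family = NA,
                       matrix = matrix(0.25, 6L, 4L)), class = "pwm")
  th <- list(score_threshold(pu))
  set.seed(8)
  occ <- scan_occurrences(random_dna(20L, 100L), th)
  expect_true(all(occ == 0L))
})

test_that("motif grouping respects the E cutoff, family guard and gene fixpoint", {
  mk <- function(name, gene, fam) new_pwm_for_tests(name, tf_gene = gene,
                                                    family = fam)
  pwms <- list(mk("m1", "GeneA", "fam1"), mk("m2", "GeneB", "fam1"),
               mk("m3", "GeneC", "fam2"), mk("m4", "GeneA", "fam2"))
  sim <- data.frame(
    motif1 = c("m1", "m1", "m3"), motif2 = c("m2", "m3", "m4"),
    evalue = c(1e-6, 1e-6, 1e-6), stringsAsFactors = FALSE)
  groups <- group_motifs(pwms, sim)
  # m1-m2 grouped (same family, E < cut); m1-m3 blocked (families differ);
  # m3-m4 grouped; then GeneA forces {m1,m2} and {m3,m4} to merge
  expect_length(groups, 1L)
  expect_setequal(groups[[1L]]$members, c("m1", "m2", "m3", "m4"))

  sim2 <- data.frame(motif1 = "m1", motif2 = "m2", evalue = 1e-6)
  pwms2 <- list(mk("m1", "GeneA", "fam1"), mk("m2", "GeneB", "fam1"),
                mk("m3", "GeneC", "fam2"))
  groups2 <- group_motifs(pwms2, sim2)
  expect_length(groups2, 2L)

  # same E but different families stay apart
  pwms3 <- list(mk("m1", "GeneA", "fam1"), mk("m2", "GeneB", "fam2"))
  groups3 <- group_motifs(pwms3, data.frame(
    motif1 = "m1", motif2 = "m2", evalue = 1e-6))
  expect_length(groups3, 2L)

  # boundary: E exactly at the cutoff does not group
  groups4 <- group_motifs(pwms3, data.frame(
    motif1 = "m1", motif2 = "m2", evalue = 1e-5))
  expect_length(groups4, 2L)
})

test_that("grouping output partitions the input independent of order", {
  set.seed(21)
  pwms <- random_pwms(8L, seed = 2L)
  for (i in 5:8) pwms[[i]]$tf_gene <- paste0("Tf", i - 4L)  # duplicate genes
  sim <- motif_similarity(pwms)
  ref <- group_motifs(pwms, sim)
  ref_sets <- lapply(ref, `[[`, "members")
  all_members <- sort(unlist(ref_sets))
  expect_equal(all_members, sort(vapply(pwms, `[[`, "", "name")))
  genes_per_group <- unlist(lapply(ref, `[[`, "genes"))
  expect_false(anyDuplicated(genes_per_group) > 0L)
  for (rep in 1:10) {
    perm <- sample(seq_along(pwms))
    got <- group_motifs(pwms[perm], sim)
    got_sets <- lapply(got, function(g) sort(g$members))
    expect_setequal(lapply(ref_sets, sort), got_sets)
  }
})

test_that("enrichment filter matches the one-sided Fisher test", {
  mk_mat <- function(n, k) {
    m <- matrix(0L, n, 1L, dimnames = list(NULL, "g1"))
    m[seq_len(k), 1L] <- 1L
    m
  }
  res <- enrichment_filter(mk_mat(1000L, 500L), mk_mat(1000L, 50L))
  expect_true(res$keep)
  expect_equal(res$p, stats::fisher.test(
    matrix(c(500L, 500L, 50L, 950L), 2L, byrow = TRUE),
    alternative = "greater")$p.value, tolerance = 1e-10)

  res2 <- enrichment_filter(mk_mat(1000L, 100L), mk_mat(1000L, 100L))
  expect_false(res2$keep)

  res3 <- enrichment_filter(mk_mat(1000L, 0L), mk_mat(1000L, 0L))
  expect_equal(res3$p, 1)
  expect_false(res3$keep)
})

test_that("prevalence filter drops columns below 2% and errors when empty", {
  m <- matrix(0L, 1000L, 2L, dimnames = list(NULL, c("a", "b")))
  m[1:19, 1L] <- 1L   # 1.9%
  m[1:20, 2L] <- 1L   # 2.0%
  out <- prevalence_filter(m)
  expect_equal(colnames(out), "b")
  expect_equal(prevalence_filter(out), out)
  expect_error(prevalence_filter(m[, 1L, drop = FALSE]), "prevalence")
})

test_that("representatives maximize occurrence fraction with name tie-break", {
  occ <- cbind(m1 = c(1L, 0L, 0L, 0L), m2 = c(1L, 1L, 1L, 0L))
  grp <- list(group_id = "g", members = c("m1", "m2"), genes = "GeneA")
  expect_equal(pick_representative(grp, occ), "m2")
  occ_tie <- cbind(mB = c(1L, 0L), mA = c(0L, 1L))
  expect_equal(pick_representative(
    list(group_id = "g", members = c("mB", "mA"), genes = "G"), occ_tie),
    "mA")
  expect_equal(pick_representative(
    list(group_id = "g", members = "mB", genes = "G"), occ_tie), "mB")
})

test_that("dinucleotide shuffling preserves dinucleotide composition", {
  set.seed(31)
  for (s in random_dna(10L, 80L)) {
    sh <- dinuc_shuffle(s)
    expect_equal(nchar(sh), nchar(s))
    expect_equal(dinuc_counts(sh), dinuc_counts(s))
    expect_equal(substr(sh, 1L, 1L), substr(s, 1L, 1L))
  }
})

test_that("the staged catalog keeps planted motifs and drops rare ones", {
  cfg <- sim_config(seed = 6L, n_loci = 120L, n_groups = 5L,
                    multi_summit_frac = 0, placement_prob = 0.4)
  sim <- simulate_peak_calls(cfg)
  atlas <- build_atlas(do.call(rbind, lapply(sim$peaks, function(p) {
    p[, setdiff(names(p), "locus")]
  })))
  pwms <- random_pwms(5L, seed = 6L, sharpness = 0.97)
  # motif 5 is planted almost nowhere: prevalence filter must drop it
  cfg$placement_prob <- c(rep(0.4, 4L), 0.005)
  seqs <- simulate_sequences(atlas, pwms, cfg)$sequences
  cat <- build_motif_catalog(pwms, seqs, seed = 6L)
  kept_members <- unlist(lapply(cat$groups, `[[`, "members"))
  expect_true(all(c("motif_1", "motif_2", "motif_3", "motif_4") %in%
                    kept_members))
  expect_false("motif_5" %in% colnames(cat$matrix) &&
                 mean(cat$occurrences[, "motif_5"]) < 0.02)
  expect_true(all(cat$matrix %in% c(0L, 1L)))
})
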