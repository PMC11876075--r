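test_that("generation is fully deterministic under a fixed config", {
  cfg <- sim_config(seed = 20L, n_loci = 40L, n_genes = 200L,
                    n_cells = 100L, n_clones = 30L)
  a <- simulate_peak_calls(cfg)
  b <- simulate_peak_calls(cfg)
  expect_identical(a, b)
  atlas <- build_atlas(do.call(rbind, lapply(a$peaks, function(p) {
    p[, setdiff(names(p), "locus")]
  })))
  pwms <- random_pwms(4L, seed = 20L)
  expect_identical(simulate_sequences(atlas, pwms, cfg),
                   simulate_sequences(atlas, pwms, cfg))
  expect_identical(simulate_bulk_counts(cfg), simulate_bulk_counts(cfg))
  expect_identical(simulate_clonotypes(cfg)$records,
                   simulate_clonotypes(cfg)$records)
})

test_that("zero jitter gives identical replicate peaks and all-case-A merges", {
  cfg <- sim_config(seed = 21L, n_loci = 25L, jitter_sd = 0,
                    multi_summit_frac = 0)
  sim <- simulate_peak_calls(cfg)
  pk <- do.call(rbind, lapply(sim$peaks, function(p) {
    p[, setdiff(names(p), "locus")]
  }))
  atlas <- build_atlas(pk)
  expect_equal(nrow(atlas), 25L)
  expect_true(all(atlas$merge_case == "A"))
  expect_true(all(atlas$n_source_peaks == cfg$n_populations))

  empty <- simulate_peak_calls(sim_config(seed = 21L, n_loci = 0L))
  expect_true(all(vapply(empty$peaks, nrow, 0L) == 0L))
})

test_that("multi-summit loci exercise the split rule", {
  cfg <- sim_config(seed = 22L, n_loci = 20L, multi_summit_frac = 1)
  sim <- simulate_peak_calls(cfg)
  atlas <- build_atlas(do.call(rbind, lapply(sim$peaks, function(p) {
    p[, setdiff(names(p), "locus")]
  })))
  expect_true(any(atlas$merge_case == "B"))
  expect_true(all(atlas$summit >= atlas$start & atlas$summit < atlas$end))
})

test_that("emitted peak files round-trip through the narrowPeak reader", {
  cfg <- sim_config(seed = 23L, n_loci = 15L)
  sim <- simulate_peak_calls(cfg)
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  write_atlas(sim$peaks[[1L]], f)
  back <- read_narrowpeak(f, source = "pop1")
  expect_equal(back[, c("chrom", "start", "end", "summit")],
               sim$peaks[[1L]][, c("chrom", "start", "end", "summit")])
})

test_that("planted motif instances drive scan occupancy as configured", {
  cfg <- sim_config(seed = 24L, n_loci = 60L, multi_summit_frac = 0,
                    n_groups = 2L, placement_prob = 1)
  sim <- simulate_peak_calls(cfg)
  atlas <- build_atlas(do.call(rbind, lapply(sim$peaks, function(p) {
    p[, setdiff(names(p), "locus")]
  })))
  pwms <- random_pwms(2L, seed = 24L, sharpness = 0.97)
  seq1 <- simulate_sequences(atlas, pwms, cfg)
  th <- lapply(pwms, score_threshold)
  occ <- scan_occurrences(seq1$sequences, th)
  expect_true(all(occ[, 1L] == 1L))  # placement_prob 1: every peak hit

  cfg0 <- cfg; cfg0$placement_prob <- 0
  seq0 <- simulate_sequences(atlas, pwms, cfg0)
  occ0 <- scan_occurrences(seq0$sequences, th)
  # false-positive bound: p * 2 * (width - L + 1) per peak
  width <- max(atlas$end - atlas$start)
  bound <- 1e-4 * 2 * (width - 8 + 1)
  expect_lte(mean(occ0), 3 * bound + 0.02)
  expect_equal(nrow(seq0$placements), 0L)
})

test_that("noiseless accessibility is exactly linear in motif presence", {
  set.seed(25)
  X <- matrix(rbinom(600L * 6L, 1L, 0.4), 600L, 6L,
              dimnames = list(paste0("peak_", 1:600), paste0("g", 1:6)))
  cfg <- sim_config(seed = 25L, noise_sd = 0)
  acc <- simulate_accessibility(X, cfg)
  expect_equal(acc$diff$log2fc_svn, unname(acc$truth$signal_svn))
  fit <- fit_ridge(X, acc$diff$log2fc_svn, lambda = 0)
  expect_equal(unname(fit$coefficients), acc$truth$beta_svn,
               tolerance = 1e-8)
  expect_true(all(acc$diff$padj_svn >= 0 & acc$diff$padj_svn <= 1))

  # identical planted betas for both comparisons: concordance -> 1
  conc <- shared_fc_concordance(acc$diff)
  expect_equal(conc$r, 1, tolerance = 1e-12)
})

test_that("bulk counts approach Poisson as dispersion vanishes", {
  cfg <- sim_config(seed = 26L, n_genes = 2000L, nb_dispersion = 0)
  sim <- simulate_bulk_counts(cfg, effect_size = 0, frac_de = 0)
  counts <- sim$expr$values  # FPKM-scaled, but variance ratio is scale-free
  vm <- apply(counts, 1L, var) / (rowMeans(counts) + 1e-9)
  cfg2 <- sim_config(seed = 26L, n_genes = 2000L, nb_dispersion = 0.5)
  sim2 <- simulate_bulk_counts(cfg2, effect_size = 0, frac_de = 0)
  vm2 <- apply(sim2$expr$values, 1L, var) /
    (rowMeans(sim2$expr$values) + 1e-9)
  # overdispersed generator inflates variance relative to the Poisson one
  expect_gt(median(vm2), 3 * median(vm))
})

test_that("bulk simulation plants the floor gene and segment genes", {
  cfg <- sim_config(seed = 27L, n_genes = 400L)
  sim <- simulate_bulk_counts(cfg)
  expect_true("Cd8a" %in% rownames(sim$expr$values))
  kept <- filter_genes(sim$expr)
  expect_false(any(grepl("^(Ig[hkl][vdj]|Tr[abgd][vdj])", kept)))
  expect_false(any(grepl("^LowGene", kept)))  # planted below the floor
  expect_equal(length(sim$expr$populations), 9L)  # 3 populations x 3 reps
})

test_that("single-cell programs separate in module-score space", {
  cfg <- sim_config(seed = 28L, n_cells = 300L, program_effect = 6)
  sim <- simulate_cells(cfg)
  lognorm <- ridgemotif:::log_normalize_counts(sim$counts)
  p1 <- sim$truth$programs[[1L]]
  sc <- module_score(lognorm, p1, seed = 28L)
  in1 <- sim$cells$program == names(sim$truth$programs)[1L]
  expect_gt(mean(sc[in1]) - mean(sc[!in1]), 0.2)
  t <- stats::t.test(sc[in1], sc[!in1])
  expect_lt(t$p.value, 1e-6)

  # no program effect: scores indistinguishable between programs
  cfg0 <- sim_config(seed = 28L, n_cells = 300L, program_effect = 1)
  sim0 <- simulate_cells(cfg0)
  sc0 <- module_score(ridgemotif:::log_normalize_counts(sim0$counts),
                      sim0$truth$programs[[1L]], seed = 28L)
  in0 <- sim0$cells$program == names(sim0$truth$programs)[1L]
  expect_gt(stats::t.test(sc0[in0], sc0[!in0])$p.value, 0.01)
})

test_that("clonotype tables realize the planted overlap targets", {
  target <- matrix(0.02, 4, 4)
  target[1, 2] <- target[2, 1] <- 0.5
  diag(target) <- 1
  dimnames(target) <- rep(list(paste0("ph", 1:4)), 2L)
  cfg <- sim_config(seed = 29L, n_mice = 1L, n_clones = 500L,
                    clonal_overlap_target = target)
  sim <- simulate_clonotypes(cfg)
  ct <- call_clonotypes(sim$records)
  J <- overlap_matrices(ct)$pooled
  expect_lt(abs(J["ph1", "ph2"] - 0.5), 0.1)
  expect_true(all(abs(J[upper.tri(J)][-1L] - 0.02) < 0.05))

  ident <- diag(4)
  dimnames(ident) <- dimnames(target)
  cfg_i <- sim_config(seed = 29L, n_mice = 1L, n_clones = 500L,
                      clonal_overlap_target = ident)
  Ji <- overlap_matrices(call_clonotypes(
    simulate_clonotypes(cfg_i)$records))$pooled
  expect_true(all(Ji[upper.tri(Ji)] < 0.05))

  bad <- target; bad[1, 2] <- bad[2, 1] <- 1.0
  expect_error(sim_config(seed = 1L, clonal_overlap_target = bad),
               "infeasible")
  asym <- target; asym[1, 2] <- 0.3
  expect_error(sim_config(seed = 1L, clonal_overlap_target = asym),
               "symmetric")
})
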