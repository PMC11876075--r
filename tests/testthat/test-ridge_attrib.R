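sim_xy <- function(seed, n = 400L, p = 10L, betas = c(0.8, 0.5, -0.8),
                   noise_sd = 0.5, prob = 0.3) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 1L, prob), n, p,
              dimnames = list(paste0("peak_", seq_len(n)),
                              paste0("g", seq_len(p))))
  beta <- numeric(p)
  beta[seq_along(betas)] <- betas
  y <- drop(X %*% beta) + rnorm(n, 0, noise_sd)
  list(X = X, y = y, beta = beta)
}

test_that("lambda = 0 reproduces ordinary least squares", {
  d <- sim_xy(1L)
  fit <- fit_ridge(d$X, d$y, lambda = 0)
  ols <- stats::lm(d$y ~ d$X)
  expect_equal(unname(fit$coefficients), unname(coef(ols)[-1L]),
               tolerance = 1e-10)
  expect_equal(fit$intercept, unname(coef(ols)[1L]), tolerance = 1e-10)
  expect_equal(unname(fit$fitted), unname(fitted(ols)), tolerance = 1e-10)
})

test_that("orthonormal design obeys the (1+lambda)^-1 X'y closed form", {
  set.seed(2)
  M <- qr.Q(qr(matrix(rnorm(200 * 4), 200, 4)))
  M <- scale(M, center = TRUE, scale = FALSE)
  M <- qr.Q(qr(M))  # centered orthonormal columns
  colnames(M) <- paste0("g", 1:4)
  y <- rnorm(200)
  fit <- fit_ridge(M, y, lambda = 1)
  expect_equal(unname(fit$coefficients),
               unname(drop(crossprod(M, y - mean(y)))) / 2,
               tolerance = 1e-10)
})

test_that("fixed-lambda fits equal the augmented least-squares construction", {
  d <- sim_xy(3L, n = 120L, p = 6L)
  for (lam in c(0.5, 3, 25)) {
    fit <- fit_ridge(d$X, d$y, lambda = lam)
    Xc <- scale(d$X, center = TRUE, scale = FALSE)
    yc <- d$y - mean(d$y)
    Xa <- rbind(Xc, sqrt(lam) * diag(ncol(Xc)))
    ya <- c(yc, numeric(ncol(Xc)))
    beta_aug <- qr.solve(Xa, ya)
    expect_equal(unname(fit$coefficients), unname(beta_aug),
                 tolerance = 1e-8)
  }
})

test_that("shrinkage is monotone and the large-lambda limit is the mean", {
  d <- sim_xy(4L)
  grid <- c(0, 0.1, 1, 10, 100, 1e4)
  norms <- vapply(grid, function(l) {
    sqrt(sum(fit_ridge(d$X, d$y, lambda = l)$coefficients^2))
  }, 0)
  expect_true(all(diff(norms) <= 1e-12))
  big <- fit_ridge(d$X, d$y, lambda = 1e12)
  expect_equal(unname(big$fitted), rep(mean(d$y), length(d$y)),
               tolerance = 1e-6)
  expect_error(fit_ridge(d$X, d$y, lambda = -1))
})

test_that("singular designs require a positive penalty", {
  d <- sim_xy(5L, n = 60L, p = 4L)
  X <- cbind(d$X, dup = d$X[, 1L])
  expect_error(fit_ridge(X, d$y, lambda = 0), "singular")
  expect_silent(fit <- fit_ridge(X, d$y, lambda = 1))
})

test_that("auto lambda recovers planted effects with significant p-values", {
  d <- sim_xy(6L, n = 2000L, p = 20L)
  fit <- fit_ridge(d$X, d$y)
  top3 <- names(sort(abs(fit$coefficients), decreasing = TRUE))[1:3]
  expect_setequal(top3, c("g1", "g2", "g3"))
  expect_true(all(fit$pvalues[c("g1", "g2", "g3")] < 0.001))
  expect_true(max(abs(fit$coefficients - d$beta)) < 0.15)
  expect_true(fit$lambda > 0)
  # signs of planted coefficients recovered across seeds
  ok <- vapply(11:20, function(s) {
    dd <- sim_xy(s, n = 1500L, p = 15L)
    f <- fit_ridge(dd$X, dd$y)
    all(sign(f$coefficients[1:3]) == sign(dd$beta[1:3]))
  }, FALSE)
  expect_gte(sum(ok), 9L)
})

test_that("zeroed-out models degrade fit only for informative columns", {
  d <- sim_xy(7L, n = 1500L, p = 8L)
  full <- fit_ridge(d$X, d$y)
  zeroed <- zeroed_out_fits(d$X, d$y)
  expect_length(zeroed, 8L)
  rv <- vapply(zeroed, function(f) mean(f$residuals^2), 0)
  expect_true(all(rv[1:3] > mean(full$residuals^2)))

  # single column: the zeroed model is intercept-only
  X1 <- d$X[, 1L, drop = FALSE]
  z1 <- zeroed_out_fits(X1, d$y)
  expect_equal(unname(z1[[1L]]$fitted), rep(mean(d$y), length(d$y)))

  frozen <- zeroed_out_fits(d$X, d$y, lambda_policy = "freeze", full = full)
  expect_true(all(vapply(frozen, `[[`, 0, "lambda") == full$lambda))
  expect_error(zeroed_out_fits(d$X, d$y, lambda_policy = "freeze"))
})

test_that("delta-cor is ~0 for subset-constant motifs and ranks planted ones", {
  d <- sim_xy(8L, n = 3000L, p = 12L)
  full <- fit_ridge(d$X, d$y)
  zeroed <- zeroed_out_fits(d$X, d$y)

  # saturated subset: g1 present in every subset peak, its column is
  # constant there, so withholding it shifts predictions by a constant
  sat <- which(d$X[, 1L] > 0)
  dc_sat <- delta_cor(full, zeroed, sat, d$y, d$X)
  expect_lt(abs(dc_sat$delta_cor[dc_sat$group == "g1"]), 0.02)

  # full peak set: the three planted groups dominate the attribution
  dc_all <- delta_cor(full, zeroed, seq_along(d$y), d$y, d$X)
  expect_setequal(dc_all$group[order(-dc_all$delta_cor)][1:3],
                  c("g1", "g2", "g3"))
  expect_true(all(dc_all$delta_cor[1:3] > 0))
  expect_equal(attr(dc_all, "reference_log2fc"), mean(d$y))

  # mixed (cluster-like) subset: half with g1, half without
  set.seed(88)
  mix <- c(sample(which(d$X[, 1L] > 0), 300L),
           sample(which(d$X[, 1L] == 0), 300L))
  dc_mix <- delta_cor(full, zeroed, mix, d$y, d$X)
  expect_equal(dc_mix$group[which.max(dc_mix$delta_cor)], "g1")

  expect_error(delta_cor(full, zeroed, 1:2, d$y, d$X), "at least 3")
  expect_error(delta_cor(full, zeroed, 1:5, rep(1, length(d$y)), d$X),
               "variance")
})

test_that("model comparison categorizes significance with a strict cutoff", {
  mk_fit <- function(beta, p, comparison) {
    structure(list(comparison = comparison, lambda = 1,
                   coefficients = beta, intercept = 0, pvalues = p,
                   se = p, fitted = numeric(0), residuals = numeric(0),
                   sigma2 = 1, df_residual = 10L, lambda_path = NULL,
                   n = 10L, p = length(beta)), class = "ridge_fit")
  }
  b <- c(g1 = 1, g2 = 0.5, g3 = -0.2, g4 = 0)
  svn <- mk_fit(b, c(g1 = 1e-5, g2 = 0.0011, g3 = 0.5, g4 = 1e-9), "svn")
  svr <- mk_fit(b, c(g1 = 1e-5, g2 = 0.5, g3 = 0.0009, g4 = 0.9), "svr")
  out <- compare_models(svn, svr)
  expect_equal(out$category,
               c("both", "neither", "svr-only", "svn-only"))
  # p = 0.0011 is not significant under the strict < 0.001 rule
  expect_false(out$svn_significant[out$group == "g2"])

  svr_bad <- mk_fit(c(h1 = 1), c(h1 = 0.1), "svr")
  expect_error(compare_models(svn, svr_bad), "same motif groups")
})

test_that("shared-peak concordance matches the analytic correlation", {
  d <- data.frame(feature = paste0("p", 1:6),
                  log2fc_svn = c(1, -2, 3, 0.5, -1, 2),
                  padj_svn = c(0.01, 0.01, 0.01, 0.5, 0.01, 0.01))
  d$log2fc_svr <- d$log2fc_svn
  expect_equal(shared_fc_concordance(d)$r, 1)
  d$log2fc_svr <- -d$log2fc_svn
  expect_equal(shared_fc_concordance(d)$r, -1)
  expect_equal(shared_fc_concordance(d)$n, 5L)

  # y2 = 0.6 y1 + e, sd(e) = 0.8 sd(y1): rho = 0.6/sqrt(0.36+0.64) = 0.6
  set.seed(9)
  y1 <- rnorm(2000L)
  y2 <- 0.6 * y1 + rnorm(2000L, 0, 0.8 * stats::sd(y1))
  dd <- data.frame(feature = paste0("p", 1:2000), log2fc_svn = y1,
                   log2fc_svr = y2, padj_svn = 0.01)
  expect_equal(shared_fc_concordance(dd)$r, 0.6, tolerance = 0.05)

  expect_error(shared_fc_concordance(dd[1:2, ]), "fewer than 3")
})
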