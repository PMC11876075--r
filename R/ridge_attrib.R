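# Ridge regression of per-peak differential accessibility on motif
# presence, with semi-automatic lambda selection (Cule-De Iorio style
# PCA generalization of the HKB estimator), asymptotic coefficient
# p-values, leave-one-motif-out "zeroed-out" models and delta-correlation
# attribution at peak subsets.

#' Fit a ridge regression of log2FC on motif presence
#'
#' Solves `beta = (X'X + lambda I)^-1 X'y` on column-centered X with an
#' unpenalized intercept. With `lambda = "auto"` the ridge parameter is
#' chosen by the semi-automatic principal-components estimator: for each
#' rank `r` the candidate `lambda_r = r * sigma2 / ||alpha_r||^2` is formed
#' from the first `r` principal-component regression coefficients, and the
#' candidate minimizing exact leave-one-out prediction error (PRESS) is
#' retained. Per-coefficient p-values come from the asymptotic sampling
#' variance of the ridge estimator (normal reference, two-sided).
#'
#' @param X Numeric matrix (peaks x motif groups), typically binary.
#' @param y Numeric response (per-peak log2 fold change).
#' @param lambda Nonnegative ridge penalty, or `"auto"`.
#' @param comparison Label stored on the fit (for example "svn").
#' @return A `ridge_fit` object: coefficients, intercept, `lambda`,
#'   `pvalues`, `se`, `fitted`, `sigma2`, `df_residual`, and the candidate
#'   table `lambda_path` when auto-selected.
#' @export
fit_ridge <- function(X, y, lambda = "auto", comparison = "svn") {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n > 2L)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  cm <- colMeans(X)
  Xc <- sweep(X, 2L, cm, "-")
  ybar <- mean(y)
  yc <- y - ybar
  sv <- svd(Xc)
  d <- sv$d
  pos <- d > max(d) * 1e-12
  rank <- sum(pos)
  if (rank == 0L) stop("X has no non-constant columns")
  U <- sv$u[, pos, drop = FALSE]
  V <- sv$v[, pos, drop = FALSE]
  d <- d[pos]
  uty <- drop(crossprod(U, yc))
  rss_ols <- sum(yc^2) - sum(uty^2)
  df_ols <- n - rank - 1L
  sigma2 <- if (df_ols > 0L) rss_ols / df_ols else NA_real_

  lambda_path <- NULL
  if (identical(lambda, "auto")) {
    if (!is.finite(sigma2) || sigma2 <= 0) {
      stop("cannot auto-select lambda: residual variance is not estimable")
    }
    alpha_hat <- uty / d
    cand <- vapply(seq_len(rank), function(r) {
      r * sigma2 / sum(alpha_hat[seq_len(r)]^2)
    }, 0)
    cand <- unique(cand[is.finite(cand) & cand >= 0])
    U2 <- U^2
    press <- vapply(cand, function(l) ridge_press(U, U2, d, uty, yc, n, l), 0)
    lambda_path <- data.frame(lambda = cand, press = press)
    lambda <- cand[which.min(press)]
  }
  stopifnot(is.numeric(lambda), lambda >= 0)
  if (lambda == 0 && rank < p) {
    stop("X'X is singular; lambda = 0 requires full column rank")
  }
  shrink <- d / (d^2 + lambda)
  beta <- drop(V %*% (shrink * uty))
  names(beta) <- colnames(X)
  intercept <- ybar - sum(cm * beta)
  fitted <- drop(ybar + Xc %*% beta)
  resid <- y - fitted
  # asymptotic variance of the ridge estimator:
  # Var(beta) = sigma2 * W X'X W, W = (X'X + lambda I)^-1
  # in the SVD basis this is sigma2 * V diag(d^2/(d^2+lambda)^2) V'
  se <- pv <- rep(NA_real_, p)
  if (is.finite(sigma2)) {
    var_beta <- rowSums(sweep(V^2, 2L, (d / (d^2 + lambda))^2, "*")) * sigma2
    se <- sqrt(var_beta)
    z <- beta / se
    pv <- 2 * stats::pnorm(-abs(z))
  }
  names(se) <- names(pv) <- colnames(X)
  structure(list(
    comparison = comparison, lambda = lambda, coefficients = beta,
    intercept = intercept, pvalues = pv, se = se, fitted = fitted,
    residuals = resid, sigma2 = sigma2, df_residual = df_ols,
    lambda_path = lambda_path, n = n, p = p
  ), class = "ridge_fit")
}

ridge_press <- function(U, U2, d, uty, yc, n, lambda) {
  # exact leave-one-out for ridge with unpenalized intercept:
  # H = U diag(d^2/(d^2+lambda)) U' + 1/n J
  shrink2 <- d^2 / (d^2 + lambda)
  fitted_c <- drop(U %*% (shrink2 * uty))
  h <- drop(U2 %*% shrink2) + 1 / n
  e <- yc - fitted_c
  mean((e / (1 - h))^2)
}

#' @export
print.ridge_fit <- function(x, ...) {
  cat("ridge_fit [", x$comparison, "]: n =", x$n, ", p =", x$p,
      ", lambda =", format(x$lambda, digits = 4), "\n")
  k <- sum(!is.na(x$pvalues) & x$pvalues < 0.001)
  cat("  significant coefficients (P < 0.001):", k, "\n")
  invisible(x)
}

#' @export
coef.ridge_fit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Fit all leave-one-motif-out models
#'
#' Refits the ridge model with each motif column individually removed.
#' Under the default policy the ridge parameter is re-selected per model
#' with the same estimator as the full fit; `"freeze"` reuses the full
#' model's lambda.
#'
#' @param X Peak-by-motif matrix.
#' @param y Per-peak log2FC.
#' @param lambda_policy `"reselect"` (default) or `"freeze"`.
#' @param full Optional full `ridge_fit` (required for `"freeze"`).
#' @param comparison Label for the fits.
#' @return Named list of `ridge_fit` objects, one per removed column.
#' @export
zeroed_out_fits <- function(X, y, lambda_policy = c("reselect", "freeze"),
                            full = NULL, comparison = "svn") {
  lambda_policy <- match.arg(lambda_policy)
  X <- as.matrix(X)
  if (lambda_policy == "freeze" && is.null(full)) {
    stop("lambda_policy = 'freeze' requires the full fit")
  }
  out <- lapply(seq_len(ncol(X)), function(j) {
    Xj <- X[, -j, drop = FALSE]
    if (ncol(Xj) == 0L) {
      # intercept-only: predictions collapse to mean(y)
      return(structure(list(
        comparison = comparison, lambda = NA_real_,
        coefficients = numeric(0), intercept = mean(y),
        pvalues = numeric(0), se = numeric(0),
        fitted = rep(mean(y), length(y)), residuals = y - mean(y),
        sigma2 = stats::var(y), df_residual = length(y) - 1L,
        lambda_path = NULL, n = length(y), p = 0L
      ), class = "ridge_fit"))
    }
    fit_ridge(Xj, y,
              lambda = if (lambda_policy == "freeze") full$lambda else "auto",
              comparison = comparison)
  })
  names(out) <- colnames(X)
  out
}

#' Delta-correlation motif attribution at a peak subset
#'
#' For each motif group m, `delta_cor(m)` is the Pearson correlation
#' between observed and full-model-predicted log2FC on the subset, minus
#' the same correlation for the model with m withheld. A positive value
#' means the motif disproportionately contributes to predictive accuracy
#' at those peaks. Also reports the mean observed log2FC of subset peaks
#' containing each motif and the reference mean over all subset peaks.
#'
#' @param full Full `ridge_fit`.
#' @param zeroed List from [zeroed_out_fits()].
#' @param subset Integer or logical index, or rownames, of the peak subset.
#' @param y Observed per-peak log2FC (full length).
#' @param X Peak-by-motif matrix (for the per-motif subset means).
#' @param subset_label Label stored on the report.
#' @return A `data.frame` with `group`, `delta_cor`, `subset_log2fc_mean`,
#'   `coefficient`; attribute `reference_log2fc` holds the all-subset mean.
#' @export
delta_cor <- function(full, zeroed, subset, y, X, subset_label = "subset") {
  X <- as.matrix(X)
  if (is.character(subset)) subset <- match(subset, rownames(X))
  if (is.logical(subset)) subset <- which(subset)
  stopifnot(!anyNA(subset), all(subset >= 1L), all(subset <= length(y)))
  if (length(subset) < 3L) stop("subset must contain at least 3 peaks")
  ys <- y[subset]
  if (stats::sd(ys) == 0) stop("zero variance of log2FC on the subset")
  cor_full <- stats::cor(ys, full$fitted[subset])
  groups <- names(zeroed)
  dc <- vapply(groups, function(g) {
    cor_full - stats::cor(ys, zeroed[[g]]$fitted[subset])
  }, 0)
  sub_mean <- vapply(groups, function(g) {
    has <- X[subset, g] > 0
    if (!any(has)) return(NA_real_)
    mean(ys[has])
  }, 0)
  out <- data.frame(
    group = groups, delta_cor = dc, subset_log2fc_mean = sub_mean,
    coefficient = full$coefficients[groups],
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "reference_log2fc") <- mean(ys)
  attr(out, "subset_label") <- subset_label
  attr(out, "cor_full") <- cor_full
  out
}

#' Pair the svn and svr model coefficients with significance calls
#'
#' @param svn,svr `ridge_fit` objects over the same motif groups.
#' @param alpha Significance cutoff on the raw coefficient p-values
#'   (default 0.001, strict `<`).
#' @return `data.frame` with `group`, `beta_svn`, `beta_svr`, `p_svn`,
#'   `p_svr` and `category` in neither/svn-only/svr-only/both.
#' @export
compare_models <- function(svn, svr, alpha = 0.001) {
  groups <- names(svn$coefficients)
  if (length(groups) == 0L || !setequal(groups, names(svr$coefficients))) {
    stop("the two fits must share the same motif groups")
  }
  s1 <- !is.na(svn$pvalues[groups]) & svn$pvalues[groups] < alpha
  s2 <- !is.na(svr$pvalues[groups]) & svr$pvalues[groups] < alpha
  category <- ifelse(s1 & s2, "both",
                     ifelse(s1, "svn-only", ifelse(s2, "svr-only", "neither")))
  data.frame(
    group = groups,
    beta_svn = svn$coefficients[groups], beta_svr = svr$coefficients[groups],
    p_svn = svn$pvalues[groups], p_svr = svr$pvalues[groups],
    svn_significant = s1, svr_significant = s2, category = category,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Concordance of log2FC across two comparisons at shared differential peaks
#'
#' Restricts to features significant (adjusted p below `alpha`) in the
#' first comparison and returns the Pearson correlation of the two log2FC
#' columns on that set.
#'
#' @param diff Differential table from [read_differential()].
#' @param comparisons Character pair, for example `c("svn", "svr")`.
#' @param alpha Adjusted-p cutoff defining the shared set (default 0.05).
#' @return List with `r` (Pearson) and `n` (feature count).
#' @export
shared_fc_concordance <- function(diff, comparisons = c("svn", "svr"),
                                  alpha = 0.05) {
  stopifnot(length(comparisons) == 2L)
  c1 <- comparisons[1L]; c2 <- comparisons[2L]
  fc1 <- diff[[paste0("log2fc_", c1)]]
  fc2 <- diff[[paste0("log2fc_", c2)]]
  p1 <- diff[[paste0("padj_", c1)]]
  if (is.null(fc1) || is.null(fc2) || is.null(p1)) {
    stop("differential table lacks log2fc/padj columns for ",
         paste(comparisons, collapse = ", "))
  }
  sel <- !is.na(p1) & p1 < alpha & !is.na(fc1) & !is.na(fc2)
  n <- sum(sel)
  if (n < 3L) stop("fewer than 3 shared differential features")
  list(r = stats::cor(fc1[sel], fc2[sel]), n = n)
}
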