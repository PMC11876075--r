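# Clonotype calling from chain-level CDR3 records, Jaccard overlap
# matrices between phenotype clonotype sets (pooled and per mouse), and
# the Mantel permutation test of overlap-matrix reproducibility.

#' Call clonotypes from chain-level records
#'
#' Cells sharing an identical multiset of (chain type, nucleotide CDR3)
#' pairs form one clonotype (strict mode). In `"any-chain"` mode cells are
#' merged transitively whenever they share at least one identical chain.
#' Cells with no chains remain unassigned.
#'
#' @param records Chain-level `data.frame` from [read_clonotype_table()].
#' @param match_mode `"strict"` (default) or `"any-chain"`.
#' @return List with `cells` (`data.frame` of cell_id, mouse_id, phenotype,
#'   clonotype_id) and `assigned_fraction`.
#' @export
call_clonotypes <- function(records, match_mode = c("strict", "any-chain")) {
  match_mode <- match.arg(match_mode)
  cell_meta <- unique(records[, c("cell_id", "mouse_id", "phenotype")])
  if (anyDuplicated(cell_meta$cell_id)) {
    stop("duplicate cell_id with conflicting mouse or phenotype labels")
  }
  has_chain <- nzchar(records$cdr3_nt)
  chains <- records[has_chain, , drop = FALSE]
  key_of <- function(df) {
    keys <- paste(df$chain, df$cdr3_nt, sep = ":")
    paste(sort(keys), collapse = "|")
  }
  keys <- vapply(split(chains, chains$cell_id), key_of, "")
  if (match_mode == "strict") {
    clono <- stats::setNames(match(keys, unique(keys)), names(keys))
  } else {
    # union cells sharing any single (chain, CDR3) pair
    cell_ids <- names(keys)
    parent <- seq_along(cell_ids)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    single <- paste(chains$chain, chains$cdr3_nt, sep = ":")
    for (grp in split(match(chains$cell_id, cell_ids), single)) {
      grp <- unique(grp)
      if (length(grp) > 1L) {
        roots <- vapply(grp, find, 0L)
        for (r in roots[-1L]) {
          ra <- find(roots[1L]); rb <- find(r)
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
      }
    }
    roots <- vapply(seq_along(cell_ids), find, 0L)
    clono <- stats::setNames(match(roots, unique(roots)), cell_ids)
  }
  cells <- cell_meta
  cells$clonotype_id <- clono[cells$cell_id]
  list(cells = cells,
       assigned_fraction = mean(!is.na(cells$clonotype_id)))
}

#' Jaccard overlap of two clonotype sets
#'
#' `|C1 n C2| / (|C1| + |C2| - |C1 n C2|)`; the denominator equals the
#' union size. Two empty sets give 0 with a warning.
#'
#' @param c1,c2 Vectors of clonotype ids (treated as sets).
#' @return The Jaccard overlap in `[0, 1]`.
#' @export
jaccard <- function(c1, c2) {
  c1 <- unique(c1); c2 <- unique(c2)
  inter <- length(intersect(c1, c2))
  denom <- length(c1) + length(c2) - inter
  if (denom == 0L) {
    warning("Jaccard of two empty sets; returning 0")
    return(0)
  }
  inter / denom
}

#' Pooled and per-mouse phenotype overlap matrices
#'
#' A phenotype's clonotype set is the set of clonotype ids with at least
#' one assigned cell of that phenotype (within scope). Matrices share one
#' ordered phenotype list; phenotypes empty in a scope give zero rows with
#' a warning.
#'
#' @param clonotypes Result of [call_clonotypes()].
#' @param phenotypes Optional ordered phenotype labels (default: sorted
#'   observed labels).
#' @return List with `pooled` (symmetric Jaccard matrix) and `per_mouse`
#'   (named list of matrices).
#' @export
overlap_matrices <- function(clonotypes, phenotypes = NULL) {
  cells <- clonotypes$cells
  cells <- cells[!is.na(cells$clonotype_id), , drop = FALSE]
  if (is.null(phenotypes)) phenotypes <- sort(unique(cells$phenotype))
  build <- function(df, scope) {
    sets <- lapply(phenotypes, function(p) {
      unique(df$clonotype_id[df$phenotype == p])
    })
    names(sets) <- phenotypes
    empty <- vapply(sets, length, 0L) == 0L
    if (any(empty)) {
      warning("empty phenotype(s) in scope ", scope, ": ",
              paste(phenotypes[empty], collapse = ", "))
    }
    J <- matrix(0, length(phenotypes), length(phenotypes),
                dimnames = list(phenotypes, phenotypes))
    for (i in seq_along(phenotypes)) {
      for (j in i:length(phenotypes)) {
        v <- if (empty[i] || empty[j]) 0 else
          suppressWarnings(jaccard(sets[[i]], sets[[j]]))
        J[i, j] <- J[j, i] <- v
      }
    }
    J
  }
  pooled <- build(cells, "pooled")
  per_mouse <- lapply(split(cells, cells$mouse_id), build, scope = "mouse")
  list(pooled = pooled, per_mouse = per_mouse)
}

upper_tri_vec <- function(m) m[upper.tri(m)]

#' Mantel permutation test between two overlap matrices
#'
#' Pearson correlation over the off-diagonal upper triangles; the null
#' permutes the labels of the second matrix (rows and columns jointly).
#' With at most `exact_if` labels all permutations are enumerated and the
#' p-value is the exact fraction of permutations with `r >= r_observed`
#' (one-sided greater; the identity is included). Otherwise `n_perm`
#' random permutations are drawn and `p = (1 + #{r_perm >= r_obs}) /
#' (1 + n_perm)`.
#'
#' @param A,B Symmetric matrices with identical ordered labels.
#' @param n_perm Random permutations when not exact (default 9999).
#' @param seed RNG seed for random permutations.
#' @param exact_if Enumerate exactly when labels <= this (default 8).
#' @return List with `r_observed`, `p`, `n_perm` (count or `"exact"`).
#' @export
mantel_test <- function(A, B, n_perm = 9999L, seed = 1L, exact_if = 8L) {
  stopifnot(identical(dim(A), dim(B)), nrow(A) >= 3L)
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B))) {
    stop("matrices must share the same ordered labels")
  }
  a <- upper_tri_vec(A)
  b <- upper_tri_vec(B)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance in an off-diagonal vector; Mantel r undefined")
  }
  r_obs <- stats::cor(a, b)
  n <- nrow(A)
  if (n <= exact_if) {
    perms <- all_permutations(n)
    rs <- vapply(perms, function(p) {
      stats::cor(a, upper_tri_vec(B[p, p, drop = FALSE]))
    }, 0)
    p <- mean(rs >= r_obs - 1e-12)
    return(list(r_observed = r_obs, p = p, n_perm = "exact"))
  }
  set.seed(seed)
  count <- 0L
  for (i in seq_len(n_perm)) {
    p_ <- sample.int(n)
    if (stats::cor(a, upper_tri_vec(B[p_, p_, drop = FALSE])) >=
        r_obs - 1e-12) count <- count + 1L
  }
  list(r_observed = r_obs, p = (1 + count) / (1 + n_perm), n_perm = n_perm)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (s in sub) {
      k <- k + 1L
      v <- integer(n)
      v[i] <- n
      v[-i] <- s
      out[[k]] <- v
    }
  }
  out
}

#' Pairwise Mantel reproducibility of per-mouse overlap matrices
#'
#' Runs [mantel_test()] for every mouse pair on the intersection of
#' phenotypes nonempty in both mice; pairs with fewer than 3 common
#' phenotypes are skipped with a warning.
#'
#' @param per_mouse Named list of per-mouse overlap matrices.
#' @param n_perm,seed,exact_if Passed to [mantel_test()].
#' @return `data.frame` with `mouse1`, `mouse2`, `r`, `p`, `n_phenotypes`.
#' @export
matrix_reproducibility <- function(per_mouse, n_perm = 9999L, seed = 1L,
                                   exact_if = 8L) {
  mice <- names(per_mouse)
  out <- list()
  if (length(mice) >= 2L) {
    for (i in seq_len(length(mice) - 1L)) {
      for (j in (i + 1L):length(mice)) {
        A <- per_mouse[[i]]; B <- per_mouse[[j]]
        common <- intersect(
          rownames(A)[diag(A) > 0], rownames(B)[diag(B) > 0])
        if (length(common) < 3L) {
          warning("skipping pair ", mice[i], "/", mice[j],
                  ": fewer than 3 common phenotypes")
          next
        }
        mt <- tryCatch(
          mantel_test(A[common, common], B[common, common],
                      n_perm = n_perm, seed = seed, exact_if = exact_if),
          error = function(e) NULL)
        if (is.null(mt)) {
          warning("skipping pair ", mice[i], "/", mice[j], ": ",
                  "degenerate overlap matrices")
          next
        }
        out[[length(out) + 1L]] <- data.frame(
          mouse1 = mice[i], mouse2 = mice[j], r = mt$r_observed,
          p = mt$p, n_phenotypes = length(common),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(mouse1 = character(0), mouse2 = character(0),
                      r = numeric(0), p = numeric(0),
                      n_phenotypes = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
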