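#' Multidimensional scaling on identity-by-state distances
#'
#' Pairwise IBS similarity is the mean over SNPs of `(2 - |g_i - g_j|) / 2`;
#' the distance `1 - IBS` is passed to classical metric MDS
#' (`stats::cmdscale`, double-centering + eigen-decomposition). Axes are
#' ordered by eigenvalue and the sign of each axis is fixed so that its
#' largest-magnitude coordinate is positive.
#'
#' @param geno a [geno_matrix()]; with missing calls, pairwise-complete SNPs
#'   are used per pair (`pairwise = TRUE`, the default) or an error is
#'   raised.
#' @param n_axes number of axes to return (truncated to the available rank,
#'   with a warning).
#' @param pairwise allow missing data via pairwise-complete SNP sets.
#' @return list with `points` (n x k coordinate matrix, rownames = ids),
#'   `eig` (eigenvalues) and `ibs` (the similarity matrix).
#' @export
ibs_mds <- function(geno, n_axes = 2, pairwise = TRUE) {
  v <- geno$values
  n <- nrow(v)
  if (n < 3) stopf("need at least 3 individuals for MDS")
  if (anyNA(v) && !pairwise) stopf("missing genotypes; set pairwise = TRUE")
  if (!all(v[!is.na(v)] %in% 0:2))
    stopf("IBS is defined on observed genotypes coded 0/1/2")
  if (anyNA(v)) {
    obs <- !is.na(v)
    vz <- v; vz[!obs] <- 0
    # sum over pairwise-complete SNPs of |gi - gj| via the expansion
    # |a-b| over {0,1,2}: E|a-b| decomposed with indicator cross-products
    num <- matrix(0, n, n)
    den <- tcrossprod(obs * 1)
    for (a in 0:2) for (b in 0:2) {
      if (a == b) next
      Ia <- (vz == a & obs) * 1
      Ib <- (vz == b & obs) * 1
      num <- num + abs(a - b) * tcrossprod(Ia, Ib)
    }
    d_abs <- num / pmax(den, 1)
  } else {
    # complete data: |gi-gj| summed over SNPs, via indicator cross-products
    num <- matrix(0, n, n)
    for (a in 0:2) for (b in 0:2) {
      if (a == b) next
      Ia <- (v == a) * 1
      Ib <- (v == b) * 1
      num <- num + abs(a - b) * tcrossprod(Ia, Ib)
    }
    d_abs <- num / ncol(v)
  }
  ibs <- (2 - d_abs) / 2
  dimnames(ibs) <- list(rownames(v), rownames(v))
  D <- 1 - ibs
  fit <- stats::cmdscale(stats::as.dist(D), k = min(n_axes, n - 1), eig = TRUE)
  pts <- fit$points
  rank_ok <- sum(fit$eig > 1e-9)
  if (ncol(pts) > rank_ok) {
    warnf("requested %d axes but rank is %d; truncating", n_axes, rank_ok)
    pts <- pts[, seq_len(max(rank_ok, 1)), drop = FALSE]
  } else if (n_axes > ncol(pts)) {
    warnf("requested %d axes; only %d available", n_axes, ncol(pts))
  }
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("axis", seq_len(ncol(pts)))
  list(points = pts, eig = fit$eig, ibs = ibs)
}
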