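#' Effective number of independent tests on one chromosome
#'
#' Eigen-decomposes the SNP x SNP Pearson correlation matrix
#' (pairwise-complete dosages) and returns the smallest number of principal
#' components whose eigenvalue sum reaches `variance_kept` of the total
#' (99.6% by default). Constant SNP columns are dropped with a warning.
#' When there are more SNPs than individuals and the data are complete, the
#' eigenvalues are obtained from the individual x individual dual matrix,
#' which shares the nonzero spectrum.
#'
#' @param geno [geno_matrix()] restricted to one chromosome (not enforced;
#'   use [significance_thresholds()] for per-chromosome bookkeeping).
#' @param variance_kept fraction of genotype variability to describe.
#' @return integer count of effective tests.
#' @export
effective_tests <- function(geno, variance_kept = 0.996) {
  v <- geno$values
  sds <- apply(v, 2, stats::sd, na.rm = TRUE)
  keep <- !is.na(sds) & sds > 0
  if (!all(keep)) {
    warnf("%d constant SNP column(s) dropped before the decomposition", sum(!keep))
    v <- v[, keep, drop = FALSE]
  }
  m <- ncol(v)
  if (m < 2) stopf("need at least 2 SNPs with nonzero variance")
  n <- nrow(v)
  if (!anyNA(v) && m > n) {
    z <- scale(v)                       # dual: eigen of ZZ'/(m standardised cols)
    ev <- eigen(tcrossprod(z) / (n - 1), symmetric = TRUE, only.values = TRUE)$values
  } else {
    r <- stats::cor(v, use = "pairwise.complete.obs")
    r[is.na(r)] <- 0
    diag(r) <- 1
    ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  }
  ev <- pmax(ev, 0)
  k <- which(cumsum(ev) >= variance_kept * sum(ev))[1]
  as.integer(k)
}

#' Bonferroni threshold over effective tests
#'
#' `-log10(alpha / M)` where `M` is the summed per-chromosome effective
#' number of independent tests.
#'
#' @param effective_per_chromosome positive integer counts.
#' @param alpha genome-wide type-I error (default 0.05).
#' @return list: `M`, `mlog10` (full precision), `mlog10_1dp` (one
#'   decimal, as conventionally reported).
#' @export
bonferroni_threshold <- function(effective_per_chromosome, alpha = 0.05) {
  if (any(effective_per_chromosome <= 0)) stopf("counts must be positive")
  M <- sum(effective_per_chromosome)
  t <- -log10(alpha / M)
  list(M = M, mlog10 = t, mlog10_1dp = round(t, 1))
}

#' Genome-wide and suggestive significance thresholds
#'
#' Per-chromosome effective tests (Gao-style PCA on the inter-marker
#' correlation matrix, computed on observed breeder genotypes, whose LD
#' structure the tests inherit), summed into a genome-wide Bonferroni
#' threshold; the suggestive (chromosome-wide) threshold is a fixed cutoff.
#'
#' @param geno breeder [geno_matrix()].
#' @param variance_kept see [effective_tests()].
#' @param alpha genome-wide type-I error.
#' @param suggestive_mlog10 fixed suggestive threshold (default 3).
#' @return `threshold_result` list: `per_chromosome` data.frame (chr,
#'   n_snps, n_effective), `M`, `genomewide_mlog10`, `suggestive_mlog10`.
#' @export
significance_thresholds <- function(geno, variance_kept = 0.996, alpha = 0.05,
                                    suggestive_mlog10 = 3) {
  chrs <- unique(geno$map$chr)
  per <- data.frame(chr = chrs, n_snps = NA_integer_, n_effective = NA_integer_)
  for (i in seq_along(chrs)) {
    sub <- subset_geno(geno, snps = geno$map$snp_id[geno$map$chr == chrs[i]])
    per$n_snps[i] <- ncol(sub$values)
    per$n_effective[i] <- if (per$n_snps[i] >= 2)
      effective_tests(sub, variance_kept) else per$n_snps[i]
  }
  bt <- bonferroni_threshold(per$n_effective, alpha)
  structure(list(per_chromosome = per, M = bt$M,
                 genomewide_mlog10 = bt$mlog10,
                 genomewide_mlog10_1dp = bt$mlog10_1dp,
                 suggestive_mlog10 = suggestive_mlog10),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("effective tests: %d over %d chromosome(s); genome-wide -log10 threshold %.1f (alpha-based), suggestive %.1f\n",
              x$M, nrow(x$per_chromosome), x$genomewide_mlog10_1dp,
              x$suggestive_mlog10))
  invisible(x)
}
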