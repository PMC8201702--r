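#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on genotype counts: conditional on the minor-allele
#' count, the probability of each possible heterozygote count is computed
#' and all outcomes no more probable than the observed one are summed
#' (no mid-p correction).
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (either homozygote first).
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  if (n == 0L) return(1)
  n_minor <- min(2 * n_hom1 + n_het, 2 * n_hom2 + n_het)
  hets <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  # log P(het = h | n, n_minor) up to a constant
  lp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    h * log(2) - lfactorial(hom_min) - lfactorial(h) - lfactorial(hom_maj)
  }, 0)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= obs + 1e-12]))
}

#' Genotype quality control
#'
#' Filters in a fixed order: individual call rate (CR), then SNP call
#' frequency (CF), minor allele frequency (MAF) and an exact two-sided
#' Hardy-Weinberg test computed on the retained individuals. SNPs that are
#' unmapped or not on an autosome are removed first. Intended for observed
#' breeder genotypes; parental-average dosages are not genotypes and should
#' not be HWE-tested.
#'
#' @param geno a [geno_matrix()] with values in `{0, 1, 2, NA}`.
#' @param cf_min minimum SNP call frequency (default 0.95).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param cr_min minimum individual call rate (default 0.90).
#' @param hwe_p Hardy-Weinberg exact-test p-value cutoff (default 1e-10).
#' @param autosomes chromosome labels considered autosomal; default: all
#'   numeric-like labels (X, Y, MT and unmapped removed).
#' @return list with the filtered `geno_matrix` and a `qc_report` holding
#'   `removed_snps` (snp_id, reason in call_frequency / maf / hwe /
#'   unmapped_or_sex), `removed_individuals` (id, reason call_rate) and the
#'   thresholds used.
#' @export
qc_filter <- function(geno, cf_min = 0.95, maf_min = 0.01, cr_min = 0.90,
                      hwe_p = 1e-10, autosomes = NULL) {
  v <- geno$values
  map <- geno$map
  if (!nrow(v) || !ncol(v)) stopf("empty genotype matrix")
  rm_snp <- data.frame(snp_id = character(0), reason = character(0),
                       stringsAsFactors = FALSE)
  rm_ind <- data.frame(id = character(0), reason = character(0),
                       stringsAsFactors = FALSE)
  drop_snps <- function(bad, reason) {
    if (any(bad)) {
      rm_snp <<- rbind(rm_snp, data.frame(snp_id = map$snp_id[bad],
                                          reason = reason,
                                          stringsAsFactors = FALSE))
      v <<- v[, !bad, drop = FALSE]
      map <<- map[!bad, , drop = FALSE]
      if (!ncol(v)) stopf("quality control removed every SNP (last filter: %s)", reason)
    }
  }
  # unmapped / non-autosomal SNPs
  chr <- as.character(map$chr)
  auto <- if (is.null(autosomes)) grepl("^[0-9]+$", chr) & !is.na(map$pos_bp)
          else chr %in% as.character(autosomes) & !is.na(map$pos_bp)
  drop_snps(!auto, "unmapped_or_sex")
  # individual call rate
  cr <- rowMeans(!is.na(v))
  bad_ind <- cr < cr_min
  if (any(bad_ind)) {
    rm_ind <- data.frame(id = rownames(v)[bad_ind], reason = "call_rate",
                         stringsAsFactors = FALSE)
    v <- v[!bad_ind, , drop = FALSE]
    if (!nrow(v)) stopf("quality control removed every individual (call rate)")
  }
  # SNP call frequency
  cf <- colMeans(!is.na(v))
  drop_snps(cf < cf_min, "call_frequency")
  # minor allele frequency
  f <- colMeans(v, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  drop_snps(maf < maf_min, "maf")
  # Hardy-Weinberg exact test
  hwe <- vapply(seq_len(ncol(v)), function(j) {
    x <- v[, j]
    hwe_exact_p(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                sum(x == 2, na.rm = TRUE))
  }, 0)
  drop_snps(hwe < hwe_p, "hwe")
  report <- structure(list(removed_snps = rm_snp,
                           removed_individuals = rm_ind,
                           thresholds = list(cf_min = cf_min, maf_min = maf_min,
                                             cr_min = cr_min, hwe_p = hwe_p),
                           n_snps_kept = ncol(v),
                           n_individuals_kept = nrow(v)),
                      class = "qc_report")
  out <- geno
  out$values <- v
  out$map <- map
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC report\n")
  cat(sprintf("  kept: %d individuals, %d SNPs\n",
              x$n_individuals_kept, x$n_snps_kept))
  cat(sprintf("  removed individuals (call rate < %g): %d\n",
              x$thresholds$cr_min, nrow(x$removed_individuals)))
  if (nrow(x$removed_snps)) {
    tb <- table(x$removed_snps$reason)
    for (r in names(tb)) cat(sprintf("  removed SNPs, %s: %d\n", r, tb[[r]]))
  } else cat("  removed SNPs: none\n")
  invisible(x)
}
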