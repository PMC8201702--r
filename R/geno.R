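#' Genotype matrix container
#'
#' Bundles a dosage matrix with its SNP map. Dosages count copies of the
#' *counted* allele of each SNP, fixed at load time and never re-polarised
#' afterwards, so that "allele frequency" tracks one fixed allele across
#' subsets and generations. The default orientation follows the convention
#' used throughout this pipeline: the counted allele is the major allele in
#' the cohort the data were loaded from, i.e. 0 = homozygote for the minor
#' allele, 1 = heterozygote, 2 = homozygote for the major allele.
#'
#' @param values numeric matrix, individuals in rows (rownames = ids), SNPs
#'   in columns (colnames = snp ids). Entries in `{0, 1, 2}` (observed
#'   genotypes) or `{0, 0.5, 1, 1.5, 2}` (parental-average dosages); `NA`
#'   for missing.
#' @param map data.frame with columns `snp_id`, `chr`, `pos_bp`,
#'   `allele_counted`, `allele_other`. Positions must be strictly
#'   increasing within a chromosome.
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(values, map) {
  if (!is.matrix(values)) stopf("`values` must be a matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("`values` needs individual ids as rownames and snp ids as colnames")
  need <- c("snp_id", "chr", "pos_bp")
  if (!all(need %in% names(map))) {
    stopf("map lacks column(s): %s", paste(setdiff(need, names(map)), collapse = ", "))
  }
  if (anyDuplicated(map$snp_id)) stopf("duplicated snp ids in map")
  if (!identical(colnames(values), as.character(map$snp_id)))
    stopf("map rows must match value columns (same snp ids, same order)")
  for (ch in unique(map$chr)) {
    p <- map$pos_bp[map$chr == ch]
    if (any(diff(p) <= 0)) stopf("positions not strictly increasing on chr %s", ch)
  }
  if (is.null(map$allele_counted)) map$allele_counted <- "A"
  if (is.null(map$allele_other)) map$allele_other <- "B"
  structure(list(values = values, map = as.data.frame(map)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d SNPs on %d chromosome(s); %.2f%% missing\n",
              nrow(x$values), ncol(x$values), length(unique(x$map$chr)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$values)

# restrict a geno_matrix to individuals and/or SNPs
subset_geno <- function(g, ids = NULL, snps = NULL) {
  v <- g$values
  m <- g$map
  if (!is.null(ids)) {
    miss <- setdiff(ids, rownames(v))
    if (length(miss)) stopf("unknown individual id(s): %s", paste(utils::head(miss, 5), collapse = ", "))
    v <- v[ids, , drop = FALSE]
  }
  if (!is.null(snps)) {
    keep <- match(snps, m$snp_id)
    if (anyNA(keep)) stopf("unknown snp id(s)")
    v <- v[, keep, drop = FALSE]
    m <- m[keep, , drop = FALSE]
  }
  out <- g
  out$values <- v
  out$map <- m
  out
}

#' Per-SNP allele frequencies
#'
#' Frequency of the counted allele, `mean(dosage)/2` over non-missing cells,
#' computed on observed genotypes or on parental-average dosages.
#'
#' @param geno a [geno_matrix()] (or parental-average matrix).
#' @param subset optional character vector of individual ids.
#' @return named numeric vector of frequencies in `[0, 1]`; `NA` (with a
#'   warning) for SNPs with no non-missing cell in the subset.
#' @export
allele_frequencies <- function(geno, subset = NULL) {
  v <- geno$values
  if (!is.null(subset)) {
    if (!length(subset)) stopf("`subset` must be non-empty")
    ok <- intersect(subset, rownames(v))
    if (!length(ok)) stopf("no requested individual present in the matrix")
    v <- v[ok, , drop = FALSE]
  }
  f <- colMeans(v, na.rm = TRUE) / 2
  empty <- !is.finite(f)
  if (any(empty)) {
    warnf("%d SNP(s) with no non-missing genotype in the subset; frequency set NA", sum(empty))
    f[empty] <- NA_real_
  }
  f
}

#' Inject missing genotype calls
#'
#' Masks cells independently: a SNP-wise Bernoulli rate plus an
#' individual-wise Bernoulli rate (a cell is missing if either draw hits).
#' The input object is not modified.
#'
#' @param geno a [geno_matrix()].
#' @param snp_miss_rate,ind_miss_rate fractions in `[0, 1)`.
#' @param seed integer seed.
#' @return a new `geno_matrix` with `NA`s injected.
#' @export
inject_missingness <- function(geno, snp_miss_rate = 0, ind_miss_rate = 0, seed = 1L) {
  for (r in c(snp_miss_rate, ind_miss_rate)) {
    if (!is.finite(r) || r < 0 || r >= 1) stopf("missingness rates must lie in [0, 1)")
  }
  v <- geno$values
  set.seed(derive_seed(seed, 421L))
  if (snp_miss_rate > 0) {
    hit <- matrix(stats::runif(length(v)) < snp_miss_rate, nrow(v))
    v[hit] <- NA_real_
  }
  if (ind_miss_rate > 0) {
    hit <- matrix(stats::runif(length(v)) < ind_miss_rate, nrow(v))
    v[hit] <- NA_real_
  }
  out <- geno
  out$values <- v
  out
}
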