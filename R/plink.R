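#' Read PLINK text genotypes (.ped/.map)
#'
#' Whitespace-delimited PLINK text format: the .map file gives chromosome,
#' SNP id, genetic position and physical position; the .ped file gives six
#' pedigree columns (family, id, sire, dam, sex, phenotype) followed by two
#' allele calls per SNP (`0` = missing). Dosages are oriented at load time
#' and never re-polarised afterwards: with `coding = "major"` (the
#' convention used throughout this pipeline) the counted allele is the major
#' allele, so 0 = homozygote for the minor allele, 2 = homozygote for the
#' major allele; `coding = "minor"` counts the minor allele instead. The
#' orientation is recorded in the map (`allele_counted`).
#'
#' @param prefix path prefix; reads `<prefix>.ped` and `<prefix>.map`.
#' @param coding which allele the dosage counts.
#' @return a [geno_matrix()].
#' @export
read_plink <- function(prefix, coding = c("major", "minor")) {
  coding <- match.arg(coding)
  map_f <- paste0(prefix, ".map")
  ped_f <- paste0(prefix, ".ped")
  for (f in c(map_f, ped_f)) if (!file.exists(f)) stopf("file not found: %s", f)
  mp <- utils::read.table(map_f, stringsAsFactors = FALSE,
                          col.names = c("chr", "snp_id", "cm", "pos_bp"))
  pd <- utils::read.table(ped_f, stringsAsFactors = FALSE, colClasses = "character")
  m <- nrow(mp)
  if (ncol(pd) != 6 + 2 * m)
    stopf(".ped has %d columns; expected %d for %d SNPs", ncol(pd), 6 + 2 * m, m)
  ids <- pd[[2]]
  a1 <- as.matrix(pd[, 6 + 2 * seq_len(m) - 1, drop = FALSE])
  a2 <- as.matrix(pd[, 6 + 2 * seq_len(m), drop = FALSE])
  a1[a1 == "0"] <- NA; a2[a2 == "0"] <- NA
  values <- matrix(NA_real_, length(ids), m, dimnames = list(ids, mp$snp_id))
  counted <- other <- character(m)
  for (j in seq_len(m)) {
    al <- c(a1[, j], a2[, j])
    tab <- sort(table(al), decreasing = TRUE)
    if (length(tab) > 2) stopf("SNP %s has more than two alleles", mp$snp_id[j])
    maj <- names(tab)[1]
    mino <- if (length(tab) == 2) names(tab)[2] else "."
    cnt <- if (coding == "major") maj else mino
    counted[j] <- cnt
    other[j] <- if (coding == "major") mino else maj
    values[, j] <- (a1[, j] == cnt) + (a2[, j] == cnt)
  }
  map <- data.frame(snp_id = mp$snp_id, chr = mp$chr, pos_bp = mp$pos_bp,
                    allele_counted = counted, allele_other = other,
                    stringsAsFactors = FALSE)
  geno_matrix(values, map)
}

#' Write PLINK text genotypes (.ped/.map)
#'
#' Inverse of [read_plink()]; allele letters are taken from the map. Only
#' observed genotype matrices (integer dosages) can be written.
#'
#' @param geno a [geno_matrix()] with values in `{0, 1, 2, NA}`.
#' @param prefix output path prefix.
#' @param ped optional pedigree data.frame supplying sire/dam/sex columns.
#' @return the prefix, invisibly.
#' @export
write_plink <- function(geno, prefix, ped = NULL) {
  v <- geno$values
  if (!all(v[!is.na(v)] %in% 0:2)) stopf("can only write 0/1/2 genotypes")
  map <- geno$map
  utils::write.table(
    data.frame(map$chr, map$snp_id, 0, map$pos_bp),
    paste0(prefix, ".map"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  ids <- rownames(v)
  sire <- dam <- rep("0", length(ids)); sex <- rep("0", length(ids))
  if (!is.null(ped)) {
    i <- match(ids, ped$id)
    sire <- ifelse(is.na(i) | is.na(ped$sire[i]), "0", ped$sire[i])
    dam <- ifelse(is.na(i) | is.na(ped$dam[i]), "0", ped$dam[i])
    sex <- ifelse(is.na(i), "0", ifelse(ped$sex[i] == "M", "1", "2"))
  }
  cnt <- map$allele_counted; oth <- map$allele_other
  lines <- vapply(seq_along(ids), function(r) {
    g <- v[r, ]
    h1 <- ifelse(is.na(g), "0", ifelse(g >= 1, cnt, oth))
    h2 <- ifelse(is.na(g), "0", ifelse(g == 2, cnt, oth))
    paste(c("FAM", ids[r], sire[r], dam[r], sex[r], "-9",
            rbind(h1, h2)), collapse = " ")
  }, "")
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Read / write a dosage matrix TSV
#'
#' Tab-separated individuals x SNPs table (first column `id`), used for
#' parental-average dosages; the map is supplied separately or read from a
#' `.map`-style file.
#'
#' @param path TSV path.
#' @param map SNP map data.frame (`snp_id`, `chr`, `pos_bp`).
#' @return `read_dosage_tsv`: a [geno_matrix()].
#' @export
read_dosage_tsv <- function(path, map) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = c(id = "character"))
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$id
  keep <- match(colnames(v), map$snp_id)
  if (anyNA(keep)) stopf("dosage TSV has SNPs absent from the map")
  geno_matrix(v, map[keep, , drop = FALSE])
}

#' @rdname read_dosage_tsv
#' @param geno a [geno_matrix()].
#' @export
write_dosage_tsv <- function(geno, path) {
  df <- data.frame(id = rownames(geno$values), geno$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
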