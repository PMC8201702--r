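#' Predict response-animal genotypes as parental averages
#'
#' Each ungenotyped response animal receives, per SNP, the average of its
#' sire's and dam's observed genotypes, giving dosages in
#' `{0, 0.5, 1, 1.5, 2}`; all full sibs therefore share identical rows.
#' Each cell also gets a certainty class: *certain* when the parents are
#' `(0,0)`, `(2,2)` or `(0,2)` (the offspring genotype is determined),
#' *half_certain* for `(1,1)` (value 1, true genotype 0, 1 or 2), and
#' *uncertain* for `(0,1)` or `(1,2)`. Response animals whose sire or dam is
#' absent from the genotype matrix are excluded (and listed in the
#' `excluded` attribute); a missing parental call yields a missing cell.
#'
#' @param breeders [geno_matrix()] of observed parental genotypes.
#' @param ped pedigree data.frame; rows with `role == "response"` are
#'   predicted (all rows if no `role` column).
#' @return an `avg_geno` object: a [geno_matrix()] whose `values` are
#'   parental averages, plus `certainty` (integer matrix: 2 certain, 1
#'   half_certain, 0 uncertain, NA missing) and attribute `excluded`.
#' @export
predict_average_genotypes <- function(breeders, ped) {
  v <- breeders$values
  resp <- if ("role" %in% names(ped)) ped[ped$role == "response", , drop = FALSE] else ped
  if (!nrow(resp)) stopf("no response animal in the pedigree")
  have <- rownames(v)
  ok <- !is.na(resp$sire) & !is.na(resp$dam) &
    resp$sire %in% have & resp$dam %in% have
  excluded <- as.character(resp$id[!ok])
  if (length(excluded))
    message(sprintf("excluded %d response animal(s) with ungenotyped or unknown parent",
                    length(excluded)))
  resp <- resp[ok, , drop = FALSE]
  if (!nrow(resp)) stopf("every response animal lacks genotyped parents")
  gs <- v[resp$sire, , drop = FALSE]
  gd <- v[resp$dam, , drop = FALSE]
  avg <- (gs + gd) / 2
  rownames(avg) <- resp$id
  # certainty: certain = both parents homozygous; half = both het; else uncertain
  cert <- matrix(0L, nrow(avg), ncol(avg), dimnames = dimnames(avg))
  both_hom <- (gs %% 2 == 0) & (gd %% 2 == 0)
  both_het <- (gs == 1) & (gd == 1)
  both_hom[is.na(both_hom)] <- FALSE
  both_het[is.na(both_het)] <- FALSE
  cert[both_hom] <- 2L
  cert[both_het] <- 1L
  cert[is.na(avg)] <- NA_integer_
  out <- geno_matrix(avg, breeders$map)
  out$certainty <- cert
  attr(out, "excluded") <- excluded
  class(out) <- c("avg_geno", "geno_matrix")
  out
}

#' Certainty of predicted genotypes
#'
#' A predicted cell counts as certain with weight 1 (classes 0, 2 and the
#' `0 x 2` matings giving 1) and weight 0.5 for the `1 x 1` matings (half of
#' the class-1 predictions are true genotypes).
#'
#' @param avg an `avg_geno` from [predict_average_genotypes()].
#' @return list with data.frames `per_snp` (snp_id, prop_certain) and
#'   `per_individual` (id, prop_certain), proportions over non-missing
#'   cells.
#' @export
certainty_summary <- function(avg) {
  ct <- avg$certainty
  if (is.null(ct)) stopf("not an avg_geno object (no certainty matrix)")
  w <- matrix(0, nrow(ct), ncol(ct))
  w[!is.na(ct) & ct == 2L] <- 1
  w[!is.na(ct) & ct == 1L] <- 0.5
  nm <- !is.na(ct)
  per_snp <- data.frame(snp_id = colnames(ct),
                        prop_certain = colSums(w) / pmax(colSums(nm), 1L),
                        stringsAsFactors = FALSE)
  per_ind <- data.frame(id = rownames(ct),
                        prop_certain = rowSums(w) / pmax(rowSums(nm), 1L),
                        stringsAsFactors = FALSE)
  rownames(per_snp) <- rownames(per_ind) <- NULL
  list(per_snp = per_snp, per_individual = per_ind)
}
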