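#' Build 1-Mb QTL-windows from an association scan
#'
#' The genome is divided into 1-Mb bins (`floor(pos_bp / 1e6)`, 0-based
#' half-open `[start, end)` in Mb). Bins holding at least one SNP at or
#' above the significance threshold are retained and runs of adjacent
#' retained bins on the same chromosome are merged into one window per
#' trait; the most significant SNP of each window is recorded (ties broken
#' by smaller position, then snp id).
#'
#' @param assoc `AssocResult` data.frame with `snp_id`, `chr`, `pos_bp`,
#'   `mlog10p` (genomic-control corrected) and `beta`.
#' @param threshold `-log10(p)` significance cutoff (genome-wide, e.g. 4.5).
#' @param trait,analysis optional labels copied into the output.
#' @param bridge_gap merge windows separated by this many empty bins
#'   (default 0 = touching bins only).
#' @return data.frame of windows: trait, analysis, chr, start_mb, end_mb,
#'   top_snp, top_pos_bp, top_beta, top_mlog10p, n_snps_significant.
#' @export
make_windows <- function(assoc, threshold, trait = NA_character_,
                         analysis = NA_character_, bridge_gap = 0L) {
  need <- c("snp_id", "chr", "pos_bp", "mlog10p")
  if (!all(need %in% names(assoc))) stopf("assoc lacks columns: %s",
                                          paste(setdiff(need, names(assoc)), collapse = ", "))
  sig <- assoc[!is.na(assoc$mlog10p) & assoc$mlog10p >= threshold, , drop = FALSE]
  empty <- data.frame(trait = character(0), analysis = character(0),
                      chr = character(0), start_mb = integer(0),
                      end_mb = integer(0), top_snp = character(0),
                      top_pos_bp = integer(0), top_beta = numeric(0),
                      top_mlog10p = numeric(0), n_snps_significant = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(sig)) return(empty)
  sig$bin <- floor(sig$pos_bp / 1e6)
  out <- list()
  for (ch in unique(sig$chr)) {
    s <- sig[sig$chr == ch, , drop = FALSE]
    bins <- sort(unique(s$bin))
    grp <- cumsum(c(1, diff(bins) > 1 + bridge_gap))
    for (g in unique(grp)) {
      b <- bins[grp == g]
      members <- s[s$bin %in% b, , drop = FALSE]
      o <- order(-members$mlog10p, members$pos_bp, members$snp_id)
      top <- members[o[1], ]
      out[[length(out) + 1L]] <- data.frame(
        trait = trait, analysis = analysis, chr = ch,
        start_mb = min(b), end_mb = max(b) + 1L,
        top_snp = top$snp_id, top_pos_bp = top$pos_bp,
        top_beta = if ("beta" %in% names(top)) top$beta else NA_real_,
        top_mlog10p = top$mlog10p,
        n_snps_significant = nrow(members),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Fuse QTL-windows across traits into QTL-regions
#'
#' Within one analysis, windows from all traits that overlap or touch on
#' the same chromosome are fused; each region's bounds are the envelope of
#' its member windows and, per trait present, the most significant member
#' SNP tags the (trait x region) association ("SNP-QTL").
#'
#' @param windows row-bound output of [make_windows()] across traits.
#' @return list with `regions` (region_id, chr, start_mb, end_mb, n_traits,
#'   traits) and `snp_qtl` (region_id, trait, analysis, snp_id, pos_bp,
#'   beta, mlog10p).
#' @export
fuse_regions <- function(windows) {
  if (!nrow(windows)) {
    return(list(regions = data.frame(region_id = character(0), chr = character(0),
                                     start_mb = integer(0), end_mb = integer(0),
                                     n_traits = integer(0), traits = character(0),
                                     stringsAsFactors = FALSE),
                snp_qtl = data.frame(region_id = character(0), trait = character(0),
                                     analysis = character(0), snp_id = character(0),
                                     pos_bp = integer(0), beta = numeric(0),
                                     mlog10p = numeric(0), stringsAsFactors = FALSE)))
  }
  regions <- list(); snp_qtl <- list(); rid <- 0L
  for (ch in unique(windows$chr)) {
    w <- windows[windows$chr == ch, , drop = FALSE]
    w <- w[order(w$start_mb, w$end_mb), , drop = FALSE]
    cur <- NULL
    flush <- function() {
      rid <<- rid + 1L
      id <- sprintf("R%03d", rid)
      mem <- cur$members
      regions[[length(regions) + 1L]] <<- data.frame(
        region_id = id, chr = ch, start_mb = cur$start, end_mb = cur$end,
        n_traits = length(unique(mem$trait)),
        traits = paste(sort(unique(mem$trait)), collapse = ","),
        stringsAsFactors = FALSE)
      for (tr in sort(unique(mem$trait))) {
        mt <- mem[mem$trait == tr, , drop = FALSE]
        o <- order(-mt$top_mlog10p, mt$top_pos_bp, mt$top_snp)
        t1 <- mt[o[1], ]
        snp_qtl[[length(snp_qtl) + 1L]] <<- data.frame(
          region_id = id, trait = tr, analysis = t1$analysis,
          snp_id = t1$top_snp, pos_bp = t1$top_pos_bp, beta = t1$top_beta,
          mlog10p = t1$top_mlog10p, stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(nrow(w))) {
      if (is.null(cur)) {
        cur <- list(start = w$start_mb[i], end = w$end_mb[i], members = w[i, ])
      } else if (w$start_mb[i] <= cur$end) {   # overlap or touching
        cur$end <- max(cur$end, w$end_mb[i])
        cur$members <- rbind(cur$members, w[i, ])
      } else {
        flush()
        cur <- list(start = w$start_mb[i], end = w$end_mb[i], members = w[i, ])
      }
    }
    flush()
  }
  list(regions = do.call(rbind, regions), snp_qtl = do.call(rbind, snp_qtl))
}

#' Compare QTL-regions across the global and line analyses
#'
#' Regions are matched across analyses by any chromosomal overlap (in Mb
#' bins); every SNP-QTL gets its genomic-control corrected `-log10(p)` in
#' each analysis with significance (>= genome-wide threshold) and
#' suggestive (>= suggestive threshold) flags.
#'
#' @param region_sets named list (e.g. global/HRFI/LRFI) of [fuse_regions()]
#'   outputs.
#' @param assoc_sets named list, parallel to `region_sets`, of named lists
#'   of per-trait `AssocResult` data.frames (with `mlog10p`).
#' @param genomewide_mlog10,suggestive_mlog10 thresholds.
#' @return list: `overlap` (one row per region pair/orphan: analysis,
#'   region_id, chr, start_mb, end_mb, shared_with) and `snp_qtl_lookup`
#'   (per SNP-QTL: mlog10p and flags per analysis).
#' @export
cross_analysis_compare <- function(region_sets, assoc_sets,
                                   genomewide_mlog10 = 4.5,
                                   suggestive_mlog10 = 3) {
  analyses <- names(region_sets)
  if (is.null(analyses)) stopf("region_sets must be a named list")
  all_regions <- do.call(rbind, lapply(analyses, function(a) {
    r <- region_sets[[a]]$regions
    if (!nrow(r)) return(NULL)
    r$analysis <- a
    r
  }))
  overlap <- NULL
  if (!is.null(all_regions) && nrow(all_regions)) {
    shared <- character(nrow(all_regions))
    for (i in seq_len(nrow(all_regions))) {
      ri <- all_regions[i, ]
      hit <- all_regions$analysis != ri$analysis &
        all_regions$chr == ri$chr &
        all_regions$start_mb < ri$end_mb &
        all_regions$end_mb > ri$start_mb
      shared[i] <- paste(sort(unique(all_regions$analysis[hit])), collapse = ",")
    }
    overlap <- cbind(all_regions[, c("analysis", "region_id", "chr",
                                     "start_mb", "end_mb", "traits")],
                     shared_with = shared)
  }
  lookups <- list()
  for (a in analyses) {
    sq <- region_sets[[a]]$snp_qtl
    if (!nrow(sq)) next
    for (i in seq_len(nrow(sq))) {
      row <- data.frame(discovery = a, region_id = sq$region_id[i],
                        trait = sq$trait[i], snp_id = sq$snp_id[i],
                        beta = sq$beta[i], stringsAsFactors = FALSE)
      for (b in analyses) {
        res <- assoc_sets[[b]][[sq$trait[i]]]
        ml <- if (is.null(res)) NA_real_ else
          res$mlog10p[match(sq$snp_id[i], res$snp_id)]
        row[[paste0("mlog10p_", b)]] <- ml
        row[[paste0("significant_", b)]] <- !is.na(ml) && ml >= genomewide_mlog10
        row[[paste0("suggestive_", b)]] <- !is.na(ml) && ml >= suggestive_mlog10
      }
      lookups[[length(lookups) + 1L]] <- row
    }
  }
  list(overlap = overlap,
       snp_qtl_lookup = if (length(lookups)) do.call(rbind, lookups) else NULL)
}
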