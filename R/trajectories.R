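#' Cumulative allele-frequency trajectory of one SNP in one line
#'
#' `f_g` is the frequency of the counted allele among the response animals
#' of generations 1..g combined (animals are added one generation at a
#' time, starting from G1 only), estimated from parental-average dosages.
#'
#' @param avg `avg_geno` dosages of response animals.
#' @param ped pedigree data.frame (for line and generation).
#' @param snp snp id (or vector of ids).
#' @param line line label.
#' @param generations generations to accumulate (default 1..max present).
#' @return if one snp: named numeric vector `f1..fG`; if several: a matrix
#'   (snps x generations).
#' @export
cumulative_frequencies <- function(avg, ped, snp, line,
                                   generations = NULL) {
  idx <- match(snp, avg$map$snp_id)
  if (anyNA(idx)) stopf("unknown snp id(s)")
  resp <- ped[ped$role == "response" & !is.na(ped$line) & ped$line == line, ]
  resp <- resp[resp$id %in% rownames(avg$values), ]
  if (is.null(generations)) generations <- sort(unique(resp$generation))
  if (!length(generations)) stopf("no response animals with predicted genotypes in line %s", line)
  gap <- setdiff(seq(min(generations), max(generations)), unique(resp$generation))
  if (length(gap)) stopf("no response animals in generation(s): %s",
                         paste(gap, collapse = ", "))
  V <- avg$values[, idx, drop = FALSE]
  fmat <- matrix(NA_real_, length(idx), length(generations),
                 dimnames = list(avg$map$snp_id[idx], paste0("f", generations)))
  csum <- numeric(length(idx)); cnt <- numeric(length(idx))
  for (k in seq_along(generations)) {
    ids <- resp$id[resp$generation == generations[k]]
    vg <- V[ids, , drop = FALSE]
    csum <- csum + colSums(vg, na.rm = TRUE)
    cnt <- cnt + colSums(!is.na(vg))
    fmat[, k] <- ifelse(cnt > 0, csum / (2 * cnt), NA_real_)
  }
  if (length(idx) == 1L) fmat[1, ] else fmat
}

#' Slope test of an allele-frequency trajectory
#'
#' Simple linear regression of the cumulative frequencies on generation
#' number; the Wald statistic `slope/se` is referred to a t distribution
#' with `n - 2` df (`reference = "normal"` uses the standard normal
#' instead). A flat trajectory returns slope 0 with p = 1; an exact line
#' has its standard error guarded to a small epsilon.
#'
#' @param f numeric vector of frequencies (names or `generations` give the
#'   generation numbers; default `1:length(f)`).
#' @param generations generation numbers.
#' @param reference `"t"` (df = n-2) or `"normal"`.
#' @return list: `slope` (frequency change per generation), `se`, `wald_p`,
#'   `significant` (p < 0.05).
#' @export
slope_test <- function(f, generations = seq_along(f), reference = c("t", "normal")) {
  reference <- match.arg(reference)
  ok <- is.finite(f)
  f <- f[ok]; g <- generations[ok]
  n <- length(f)
  if (n < 3) stopf("need at least 3 points")
  if (stats::var(f) == 0) {
    return(list(slope = 0, se = NA_real_, wald_p = 1, significant = FALSE))
  }
  gx <- g - mean(g)
  slope <- sum(gx * f) / sum(gx^2)
  res <- f - mean(f) - slope * gx
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(max(s2 / sum(gx^2), .Machine$double.eps))
  w <- slope / se
  p <- if (reference == "t") 2 * stats::pt(abs(w), df = n - 2, lower.tail = FALSE)
       else 2 * stats::pnorm(abs(w), lower.tail = FALSE)
  list(slope = slope, se = se, wald_p = p, significant = p < 0.05)
}

#' Classify the evolution of a SNP-QTL across the two lines
#'
#' Four cases from the two per-line slope tests: *no_change* (neither slope
#' significant), *co_selected* (both significant, same sign), *opposite*
#' (both significant, different signs), *one_line_only* otherwise. The
#' evolution score is `n_generations * (|slope_HRFI| + |slope_LRFI|)` using
#' only significant slopes (non-significant slopes contribute 0), an
#' approximation of the total frequency change over the experiment.
#'
#' @param fit_hrfi,fit_lrfi outputs of [slope_test()] for the two lines.
#' @param n_generations scale factor of the score (default 9).
#' @return list: `category`, `which_line` (for one_line_only, else NA),
#'   `evolution_score`, per-line slopes and significance.
#' @export
classify_evolution <- function(fit_hrfi, fit_lrfi, n_generations = 9) {
  sh <- isTRUE(fit_hrfi$significant); sl <- isTRUE(fit_lrfi$significant)
  category <- if (!sh && !sl) "no_change"
    else if (sh && sl && sign(fit_hrfi$slope) == sign(fit_lrfi$slope)) "co_selected"
    else if (sh && sl) "opposite"
    else "one_line_only"
  score <- n_generations * (abs(fit_hrfi$slope) * sh + abs(fit_lrfi$slope) * sl)
  list(category = category,
       which_line = if (category == "one_line_only") c("HRFI", "LRFI")[c(sh, sl)] else NA_character_,
       evolution_score = score,
       slope_hrfi = fit_hrfi$slope, slope_lrfi = fit_lrfi$slope,
       significant_hrfi = sh, significant_lrfi = sl)
}

#' Per-trait evolution summary and its link to the selection response
#'
#' Averages SNP-QTL evolution scores within trait and correlates the
#' per-trait means with the realised between-line genetic differences
#' (in genetic standard deviations).
#'
#' @param records data.frame with columns `trait` and `evolution_score`
#'   (one row per SNP-QTL).
#' @param line_differences named numeric vector, per-trait G9 genetic
#'   difference in sigma_g (e.g. `divsel_trait_table()$g9_diff_sigma_g`).
#' @return list: `per_trait` (trait, n_snp_qtl, mean_score, line_difference)
#'   and `correlation` (Pearson; NA with a warning if undefined).
#' @export
trait_evolution_summary <- function(records, line_differences) {
  if (!nrow(records)) stopf("no SNP-QTL records")
  traits <- sort(unique(records$trait))
  per <- data.frame(trait = traits,
                    n_snp_qtl = as.integer(table(records$trait)[traits]),
                    mean_score = vapply(traits, function(t)
                      mean(records$evolution_score[records$trait == t]), 0),
                    stringsAsFactors = FALSE)
  per$line_difference <- line_differences[per$trait]
  miss <- per$trait[is.na(per$line_difference)]
  if (length(miss)) {
    message(sprintf("no line difference supplied for: %s (omitted)",
                    paste(miss, collapse = ", ")))
  }
  use <- !is.na(per$line_difference)
  correlation <- NA_real_
  if (sum(use) >= 2 && stats::sd(per$mean_score[use]) > 0 &&
      stats::sd(per$line_difference[use]) > 0) {
    correlation <- stats::cor(per$mean_score[use], per$line_difference[use])
  } else {
    warnf("correlation undefined (fewer than 2 traits or zero variance); reported NA")
  }
  rownames(per) <- NULL
  list(per_trait = per, correlation = correlation)
}

#' Wright-Fisher drift standard deviation
#'
#' Closed form for the standard deviation of the allele frequency after `t`
#' generations of binomial resampling in an idealised population (panmixia,
#' no selection, `2 n_e` gene copies):
#' `sqrt(p0 (1 - p0) (1 - (1 - 1/(2 n_e))^t))`.
#'
#' @param p0 initial frequency in (0, 1).
#' @param n_e population size per generation (the reference uses N = 40).
#' @param t generations.
#' @return standard deviation of the generation-`t` frequency.
#' @export
drift_sd <- function(p0, n_e = 40, t = 9) {
  if (any(p0 <= 0 | p0 >= 1)) stopf("p0 must lie in (0, 1)")
  if (any(n_e < 1) || any(t < 0)) stopf("need n_e >= 1 and t >= 0")
  sqrt(p0 * (1 - p0) * (1 - (1 - 1 / (2 * n_e))^t))
}

#' Monte-Carlo companion of [drift_sd()]
#'
#' Binomial resampling of `2 n_e` gene copies per generation.
#'
#' @inheritParams drift_sd
#' @param n_rep replicate populations.
#' @param seed integer seed.
#' @return list: `sd` (empirical SD of the generation-`t` frequency),
#'   `freqs` (the replicate frequencies).
#' @export
drift_sim <- function(p0, n_e = 40, t = 9, n_rep = 1e5, seed = 1L) {
  if (p0 <= 0 || p0 >= 1) stopf("p0 must lie in (0, 1)")
  set.seed(derive_seed(seed, 11L))
  f <- rep(p0, n_rep)
  for (g in seq_len(t)) f <- stats::rbinom(n_rep, 2 * n_e, f) / (2 * n_e)
  list(sd = stats::sd(f), freqs = f)
}

#' Between-line allele-frequency difference at G1
#'
#' Absolute difference of the counted-allele frequency between the two
#' lines' G1 response cohorts (the earliest measurement of line
#' divergence).
#'
#' @param avg `avg_geno` dosages of response animals.
#' @param ped pedigree data.frame.
#' @param snp snp id (vectorised).
#' @return named numeric vector of |freq_HRFI - freq_LRFI|.
#' @export
g1_line_difference <- function(avg, ped, snp) {
  f <- lapply(c("HRFI", "LRFI"), function(ln) {
    ids <- ped$id[ped$role == "response" & !is.na(ped$line) &
                    ped$line == ln & ped$generation == 1]
    ids <- intersect(ids, rownames(avg$values))
    if (!length(ids)) stopf("no G1 response animals in line %s", ln)
    allele_frequencies(subset_geno(avg, snps = snp), subset = ids)
  })
  abs(f[[1]] - f[[2]])
}

#' Fit trajectories for a set of SNP-QTL and classify them
#'
#' Convenience wrapper running [cumulative_frequencies()] and [slope_test()]
#' per line and [classify_evolution()] per SNP.
#'
#' @param avg `avg_geno` of response animals.
#' @param ped pedigree data.frame.
#' @param snp_ids SNPs to fit (typically the SNP-QTL list).
#' @param n_generations score scale (default: number of generations
#'   observed).
#' @param reference passed to [slope_test()].
#' @return data.frame: snp_id, slopes/se/p per line, category, which_line,
#'   evolution_score, g1_difference.
#' @export
fit_trajectories <- function(avg, ped, snp_ids, n_generations = NULL,
                             reference = "t") {
  fH <- cumulative_frequencies(avg, ped, snp_ids, "HRFI")
  fL <- cumulative_frequencies(avg, ped, snp_ids, "LRFI")
  if (is.null(dim(fH))) { fH <- matrix(fH, 1, dimnames = list(snp_ids, names(fH))) }
  if (is.null(dim(fL))) { fL <- matrix(fL, 1, dimnames = list(snp_ids, names(fL))) }
  gens <- as.integer(sub("^f", "", colnames(fH)))
  if (is.null(n_generations)) n_generations <- length(gens)
  g1d <- g1_line_difference(avg, ped, snp_ids)
  out <- lapply(seq_along(snp_ids), function(i) {
    th <- slope_test(fH[i, ], gens, reference = reference)
    tl <- slope_test(fL[i, ], gens, reference = reference)
    cl <- classify_evolution(th, tl, n_generations)
    data.frame(snp_id = snp_ids[i],
               slope_hrfi = th$slope, se_hrfi = th$se, p_hrfi = th$wald_p,
               slope_lrfi = tl$slope, se_lrfi = tl$se, p_lrfi = tl$wald_p,
               category = cl$category,
               which_line = paste(cl$which_line, collapse = ","),
               evolution_score = cl$evolution_score,
               g1_difference = unname(g1d[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
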