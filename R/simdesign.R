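#' Configuration for the divergent-selection simulator
#'
#' Defaults reproduce the structure of the two-line residual-feed-intake
#' selection design: lines founded from 30 matings, 116 males tested at G0
#' and 96 per line per generation afterwards, 6 sires selected by truncation
#' on the selected trait (upward in HRFI, downward in LRFI), 40 randomly
#' chosen dams per line, 9 generations, response cohorts of 96 animals per
#' line per generation in G1-G5 and 175 in G6-G9, and the 24-trait panel of
#' [divsel_trait_table()]. The genome (number of SNPs, chromosome lengths)
#' is scaled to analysis needs and is set much smaller than a real SNP chip.
#'
#' All traits are simulated on a standardised scale with phenotypic
#' variance 1 before fixed effects, so `qtl_effects` and heritabilities are
#' in phenotypic-standard-deviation units.
#'
#' @param n_chromosomes,chrom_length_mb,n_snps_per_chrom genome layout.
#' @param founder_maf_range interval in (0, 0.5] for founder minor-allele
#'   frequencies (drawn uniformly per SNP).
#' @param n_founder_matings founder (F0) pairs the G0 cohort is bred from.
#' @param n_tested_males,n_tested_males_g0 male candidates phenotyped per
#'   line per generation (and in the common G0 pool).
#' @param n_selected_sires sires retained by truncation each generation.
#' @param n_dams dams per line per generation (chosen at random).
#' @param n_generations generations of selection after G0.
#' @param response_counts integer vector (length `n_generations`) of
#'   response animals per line per generation.
#' @param traits data.frame with columns `trait`, `h2`, `corr_to_selected`
#'   (and optionally `g9_diff_sigma_g`); first row must be the selected
#'   trait.
#' @param n_qtl,qtl_effects number of planted QTL and their allelic
#'   substitution effects (recycled; sign drawn at random unless effects are
#'   signed). `qtl_traits` assigns each QTL to a trait (default: the
#'   selected trait).
#' @param selection if `FALSE`, sires are picked at random (drift-only run).
#' @param sex_effect_sd,cg_effect_sd standard deviations of the simulated
#'   fixed effects (sex, contemporary group) added to response phenotypes.
#' @param recomb_rate recombination rate in cM per Mb (Haldane, no
#'   interference).
#' @param seed master seed; per-stage substreams are derived from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 18,
                       chrom_length_mb = 100,
                       n_snps_per_chrom = 100,
                       founder_maf_range = c(0.1, 0.5),
                       n_founder_matings = 30,
                       n_tested_males = 96,
                       n_tested_males_g0 = 116,
                       n_selected_sires = 6,
                       n_dams = 40,
                       n_generations = 9,
                       response_counts = c(rep(96L, 5), rep(175L, 4)),
                       traits = divsel_trait_table(),
                       n_qtl = 10,
                       qtl_effects = 0.12,
                       qtl_traits = NULL,
                       selection = TRUE,
                       sex_effect_sd = 0.2,
                       cg_effect_sd = 0.3,
                       recomb_rate = 1,
                       seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length_mb = chrom_length_mb,
              n_snps_per_chrom = as.integer(n_snps_per_chrom),
              founder_maf_range = founder_maf_range,
              n_founder_matings = as.integer(n_founder_matings),
              n_tested_males = as.integer(n_tested_males),
              n_tested_males_g0 = as.integer(n_tested_males_g0),
              n_selected_sires = as.integer(n_selected_sires),
              n_dams = as.integer(n_dams),
              n_generations = as.integer(n_generations),
              response_counts = as.integer(rep_len(response_counts, n_generations)),
              traits = as.data.frame(traits),
              n_qtl = as.integer(n_qtl),
              qtl_effects = qtl_effects,
              qtl_traits = qtl_traits,
              selection = isTRUE(selection),
              sex_effect_sd = sex_effect_sd,
              cg_effect_sd = cg_effect_sd,
              recomb_rate = recomb_rate,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_selected_sires > cfg$n_tested_males ||
      cfg$n_selected_sires * 2L > cfg$n_tested_males_g0)
    stopf("infeasible config: more sires selected (%d) than males tested",
          cfg$n_selected_sires)
  r <- cfg$founder_maf_range
  if (length(r) != 2 || r[1] <= 0 || r[2] > 0.5 || r[1] > r[2])
    stopf("founder_maf_range must lie within (0, 0.5]")
  tr <- cfg$traits
  if (!all(c("trait", "h2") %in% names(tr))) stopf("traits needs columns trait, h2")
  if (any(tr$h2 < 0 | tr$h2 > 1)) stopf("heritabilities must lie in [0, 1]")
  if (is.null(tr$corr_to_selected)) tr$corr_to_selected <- 0
  if (any(abs(tr$corr_to_selected) > 1))
    stopf("genetic correlations must lie in [-1, 1]")
  # single-factor structure: the implied trait x trait correlation matrix
  # (r_i r_j off-diagonal) is PSD whenever all |r| <= 1, checked above
  invisible(cfg)
}

# ---- internal machinery ----------------------------------------------------

# registry of simulated animals: haplotypes, pedigree fields, polygenic
# factors, selection-trait phenotype
new_registry <- function(n_max, m, n_factors) {
  reg <- new.env(parent = emptyenv())
  reg$H1 <- matrix(NA_integer_, n_max, m)
  reg$H2 <- matrix(NA_integer_, n_max, m)
  reg$u <- matrix(NA_real_, n_max, n_factors)
  reg$sire <- integer(n_max); reg$dam <- integer(n_max)
  reg$sex <- character(n_max); reg$line <- character(n_max)
  reg$gen <- integer(n_max); reg$role <- character(n_max)
  reg$Fcoef <- rep(NA_real_, n_max)
  reg$gsel <- numeric(n_max); reg$ysel <- numeric(n_max)
  reg$n <- 0L
  reg
}

# one gamete from animal i: per-chromosome Poisson crossovers, Haldane
make_gamete <- function(reg, i, gmap) {
  src <- logical(length(gmap$chr_of))      # FALSE = H1, TRUE = H2
  for (c in seq_along(gmap$idx)) {
    idx <- gmap$idx[[c]]
    phase <- stats::runif(1) < 0.5
    nco <- stats::rpois(1, gmap$lambda[c])
    if (nco == 0L) {
      src[idx] <- phase
    } else {
      xo <- sort(stats::runif(nco, 0, gmap$len_bp[c]))
      seg <- findInterval(gmap$pos[[c]], xo)
      src[idx] <- xor(phase, seg %% 2L == 1L)
    }
  }
  out <- reg$H1[i, ]
  out[src] <- reg$H2[i, src]
  out
}

# append k animals; sire/dam are registry indices (NA = founder)
add_animals <- function(reg, sire, dam, sex, line, gen, role, gmap,
                        founder_freq = NULL, sd_vec_trait) {
  k <- length(sex)
  at <- reg$n + seq_len(k)
  reg$n <- reg$n + k
  m <- ncol(reg$H1)
  if (is.null(founder_freq)) {
    for (j in seq_len(k)) {
      reg$H1[at[j], ] <- make_gamete(reg, sire[j], gmap)
      reg$H2[at[j], ] <- make_gamete(reg, dam[j], gmap)
    }
    fs <- reg$Fcoef[sire]; fd <- reg$Fcoef[dam]
    if (anyNA(fs) || anyNA(fd)) stopf("internal: parent inbreeding unknown")
    msd <- sqrt(0.5 * (1 - (fs + fd) / 2))
    reg$u[at, ] <- 0.5 * (reg$u[sire, , drop = FALSE] + reg$u[dam, , drop = FALSE]) +
      matrix(stats::rnorm(k * ncol(reg$u)), k) * msd
    reg$sire[at] <- sire; reg$dam[at] <- dam
  } else {
    reg$H1[at, ] <- matrix(stats::rbinom(k * m, 1L, rep(founder_freq, each = k)), k)
    reg$H2[at, ] <- matrix(stats::rbinom(k * m, 1L, rep(founder_freq, each = k)), k)
    reg$u[at, ] <- matrix(stats::rnorm(k * ncol(reg$u)), k)
    reg$sire[at] <- NA_integer_; reg$dam[at] <- NA_integer_
    reg$Fcoef[at] <- 0
  }
  reg$sex[at] <- sex
  reg$line[at] <- line
  reg$gen[at] <- gen
  reg$role[at] <- role
  # genetic value and selection-trait phenotype
  dos <- reg$H1[at, sd_vec_trait$qtl_cols_sel, drop = FALSE] +
    reg$H2[at, sd_vec_trait$qtl_cols_sel, drop = FALSE]
  qv <- if (length(sd_vec_trait$qtl_cols_sel))
    drop(dos %*% sd_vec_trait$qtl_eff_sel) else numeric(k)
  reg$gsel[at] <- qv + sd_vec_trait$sigma_u_sel * reg$u[at, 1]
  reg$ysel[at] <- reg$gsel[at] + stats::rnorm(k, sd = sd_vec_trait$sd_e_sel)
  at
}

# incremental breeder kinship tracker (keeps inbreeding available at mating)
new_breeder_kinship <- function(n_max_total, b_max) {
  bk <- new.env(parent = emptyenv())
  bk$A <- matrix(0, b_max, b_max)
  bk$pos <- rep(NA_integer_, n_max_total)  # registry index -> A row
  bk$n <- 0L
  bk
}

add_breeders <- function(bk, reg, idx) {
  for (i in idx) {
    p <- bk$n + 1L
    s <- reg$sire[i]; d <- reg$dam[i]
    sp <- if (is.na(s)) NA_integer_ else bk$pos[s]
    dp <- if (is.na(d)) NA_integer_ else bk$pos[d]
    if (p > 1L) {
      j <- seq_len(p - 1L)
      row <- numeric(p - 1L)
      if (!is.na(sp)) row <- row + 0.5 * bk$A[sp, j]
      if (!is.na(dp)) row <- row + 0.5 * bk$A[dp, j]
      bk$A[p, j] <- row
      bk$A[j, p] <- row
    }
    bk$A[p, p] <- 1 + if (!is.na(sp) && !is.na(dp)) 0.5 * bk$A[sp, dp] else 0
    bk$pos[i] <- p
    bk$n <- p
    reg$Fcoef[i] <- bk$A[p, p] - 1
  }
}

# ---- main entry ------------------------------------------------------------

#' Simulate the two-line divergent selection experiment
#'
#' Forward-in-time gene-drop through the breeding design: founders are drawn
#' with independent per-SNP allele frequencies (no ancestral LD; LD accrues
#' from the pedigree bottleneck), gametes are formed with Poisson crossover
#' counts per chromosome (Haldane mapping, no interference), sires are
#' chosen by truncation on their own phenotype for the selected trait (top
#' in HRFI, bottom in LRFI), and dams at random. Each generation also
#' produces response animals, whose true genotypes are returned only in the
#' validation slot `response_truth` and are withheld from the analysis
#' pipeline (their genotypes are predicted from parental averages, as in the
#' real design).
#'
#' Non-selected traits are generated from a shared polygenic factor plus a
#' trait-specific pedigree factor so that their genetic correlation to the
#' selected trait matches `traits$corr_to_selected`. Response phenotypes
#' carry simulated fixed effects (sex, contemporary group) so that the
#' adjustment stage has something to remove.
#'
#' @param config a [sim_config()].
#' @return a `sim_output` list: `pedigree` (F0 founders carry generation
#'   `-1`), `breeder_genotypes` ([geno_matrix()]), `snp_map`, `phenotypes`
#'   (response animals; traits + fixed-effect columns `sex`, `cg`),
#'   `breeder_phenotypes` (selection-trait records of breeders),
#'   `true_qtl`, `response_truth` and the `config`.
#' @export
simulate_experiment <- function(config) {
  cfg <- validate_sim_config(config)
  C <- cfg$n_chromosomes; mpc <- cfg$n_snps_per_chrom
  m <- C * mpc
  G <- cfg$n_generations
  tr <- cfg$traits
  if (is.null(tr$corr_to_selected)) tr$corr_to_selected <- 0
  Tn <- nrow(tr)
  sel_trait <- tr$trait[1]

  # --- genome map and founder frequencies ---
  set.seed(derive_seed(cfg$seed, 1L))
  len_bp <- cfg$chrom_length_mb * 1e6
  pos <- lapply(seq_len(C), function(c) sort(sample.int(len_bp - 1L, mpc)))
  map <- data.frame(
    snp_id = sprintf("snp%02d_%04d", rep(seq_len(C), each = mpc),
                     rep(seq_len(mpc), C)),
    chr = rep(seq_len(C), each = mpc),
    pos_bp = unlist(pos),
    allele_counted = "A", allele_other = "B",
    stringsAsFactors = FALSE
  )
  maf <- stats::runif(m, cfg$founder_maf_range[1], cfg$founder_maf_range[2])
  freq_counted <- 1 - maf   # counted allele = founder major allele
  gmap <- list(
    idx = split(seq_len(m), map$chr),
    pos = pos,
    chr_of = map$chr,
    len_bp = rep(len_bp, C),
    lambda = rep(cfg$chrom_length_mb * cfg$recomb_rate / 100, C)
  )

  # --- planted QTL and variance bookkeeping ---
  nq <- cfg$n_qtl
  qtl_snp <- if (nq > 0) sort(sample.int(m, nq)) else integer(0)
  eff <- rep_len(cfg$qtl_effects, max(nq, 1))[seq_len(nq)]
  if (nq > 0 && all(eff >= 0)) eff <- eff * sample(c(-1, 1), nq, TRUE)
  qtl_trait <- rep_len(cfg$qtl_traits %||% sel_trait, max(nq, 1))[seq_len(nq)]
  if (nq > 0 && !all(qtl_trait %in% tr$trait)) stopf("qtl_traits must name traits")
  true_qtl <- data.frame(snp_id = map$snp_id[qtl_snp], trait = qtl_trait,
                         effect = eff, stringsAsFactors = FALSE)
  vq <- vapply(tr$trait, function(t) {
    j <- which(qtl_trait == t)
    sum(2 * freq_counted[qtl_snp[j]] * (1 - freq_counted[qtl_snp[j]]) * eff[j]^2)
  }, 0)
  h2s <- tr$h2[1]
  if (vq[1] > h2s + 1e-12)
    stopf("QTL variance on the selected trait (%.3f) exceeds its h2 (%.3f)",
          vq[1], h2s)
  sigma_u_sel <- sqrt(max(h2s - vq[1], 0))
  r <- tr$corr_to_selected
  c_t <- if (h2s > 0) r * sqrt(tr$h2 / h2s) else rep(0, Tn)
  wvar <- tr$h2 * (1 - r^2)
  extra <- vq; extra[1] <- 0   # QTL planted directly on a non-selected trait
  if (any(extra > wvar + 1e-12))
    warnf("trait-specific QTL variance exceeds the independent genetic variance for %s",
          paste(tr$trait[extra > wvar + 1e-12], collapse = ", "))
  wvar <- pmax(wvar - extra, 0)
  sel_pack <- list(
    qtl_cols_sel = qtl_snp[qtl_trait == sel_trait],
    qtl_eff_sel = eff[qtl_trait == sel_trait],
    sigma_u_sel = sigma_u_sel,
    sd_e_sel = sqrt(max(1 - h2s, 0))
  )

  # --- registry sizing ---
  n_resp_tot <- 2L * sum(cfg$response_counts)
  n_max <- 2L * cfg$n_founder_matings + cfg$n_tested_males_g0 + 2L * cfg$n_dams +
    (G - 1L) * 2L * (cfg$n_tested_males + cfg$n_dams) + n_resp_tot
  reg <- new_registry(n_max, m, Tn)
  b_max <- 2L * cfg$n_founder_matings + 2L * (cfg$n_selected_sires + cfg$n_dams) * G
  bk <- new_breeder_kinship(n_max, b_max)

  lines <- c("HRFI", "LRFI")
  pick_sires <- function(males, line) {
    if (!cfg$selection) return(sample(males, cfg$n_selected_sires))
    y <- reg$ysel[males]
    o <- order(y, decreasing = (line == "HRFI"))
    males[o[seq_len(cfg$n_selected_sires)]]
  }

  # --- F0 founders and the common G0 cohort ---
  set.seed(derive_seed(cfg$seed, 2L))
  f0_s <- add_animals(reg, sex = rep("M", cfg$n_founder_matings), line = NA,
                      gen = -1L, role = "founder", gmap = gmap,
                      founder_freq = freq_counted, sd_vec_trait = sel_pack,
                      sire = NULL, dam = NULL)
  f0_d <- add_animals(reg, sex = rep("F", cfg$n_founder_matings), line = NA,
                      gen = -1L, role = "founder", gmap = gmap,
                      founder_freq = freq_counted, sd_vec_trait = sel_pack,
                      sire = NULL, dam = NULL)
  add_breeders(bk, reg, c(f0_s, f0_d))
  lit_m <- sample.int(cfg$n_founder_matings, cfg$n_tested_males_g0, TRUE)
  g0_m <- add_animals(reg, f0_s[lit_m], f0_d[lit_m],
                      rep("M", cfg$n_tested_males_g0), NA, 0L, "candidate",
                      gmap, sd_vec_trait = sel_pack)
  lit_f <- sample.int(cfg$n_founder_matings, 2L * cfg$n_dams, TRUE)
  g0_f <- add_animals(reg, f0_s[lit_f], f0_d[lit_f],
                      rep("F", 2L * cfg$n_dams), NA, 0L, "candidate",
                      gmap, sd_vec_trait = sel_pack)
  # the two tails of the G0 males found the lines
  o <- order(reg$ysel[g0_m], decreasing = TRUE)
  if (!cfg$selection) o <- sample(o)
  sires <- list(HRFI = g0_m[o[seq_len(cfg$n_selected_sires)]],
                LRFI = g0_m[rev(o)[seq_len(cfg$n_selected_sires)]])
  fshuf <- sample(g0_f)
  dams <- list(HRFI = fshuf[seq_len(cfg$n_dams)],
               LRFI = fshuf[cfg$n_dams + seq_len(cfg$n_dams)])
  for (ln in lines) {
    idx <- c(sires[[ln]], dams[[ln]])
    reg$line[idx] <- ln
    reg$role[idx] <- "breeder"
    add_breeders(bk, reg, idx)
  }

  resp_idx <- integer(0)
  # --- generations 1..G ---
  for (g in seq_len(G)) {
    for (li in seq_along(lines)) {
      ln <- lines[li]
      set.seed(derive_seed(cfg$seed, 100L + g * 10L + li))
      sire_of_dam <- sample(rep_len(sires[[ln]], cfg$n_dams))
      dvec <- dams[[ln]]
      nr <- cfg$response_counts[g]
      lit <- sample.int(cfg$n_dams, nr, TRUE)
      resp <- add_animals(reg, sire_of_dam[lit], dvec[lit],
                          rep_len(c("F", "M"), nr), ln, g, "response",
                          gmap, sd_vec_trait = sel_pack)
      resp_idx <- c(resp_idx, resp)
      if (g < G) {
        lit <- sample.int(cfg$n_dams, cfg$n_tested_males, TRUE)
        males <- add_animals(reg, sire_of_dam[lit], dvec[lit],
                             rep("M", cfg$n_tested_males), ln, g, "candidate",
                             gmap, sd_vec_trait = sel_pack)
        lit <- sample.int(cfg$n_dams, cfg$n_dams, TRUE)
        females <- add_animals(reg, sire_of_dam[lit], dvec[lit],
                               rep("F", cfg$n_dams), ln, g, "breeder",
                               gmap, sd_vec_trait = sel_pack)
        new_sires <- pick_sires(males, ln)
        reg$role[new_sires] <- "breeder"
        add_breeders(bk, reg, c(new_sires, females))
        sires[[ln]] <- new_sires
        dams[[ln]] <- females
      }
    }
  }

  # --- assemble outputs ---
  n <- reg$n
  ids <- sprintf("A%05d", seq_len(n))
  keep <- reg$role[seq_len(n)] != "candidate"
  ped <- data.frame(
    id = ids[seq_len(n)],
    sire = ifelse(is.na(reg$sire[seq_len(n)]), NA, ids[reg$sire[seq_len(n)]]),
    dam = ifelse(is.na(reg$dam[seq_len(n)]), NA, ids[reg$dam[seq_len(n)]]),
    sex = reg$sex[seq_len(n)],
    line = reg$line[seq_len(n)],
    generation = reg$gen[seq_len(n)],
    role = reg$role[seq_len(n)],
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(ped) <- NULL

  dosage <- function(idx) {
    v <- reg$H1[idx, , drop = FALSE] + reg$H2[idx, , drop = FALSE]
    storage.mode(v) <- "double"
    rownames(v) <- ids[idx]
    colnames(v) <- map$snp_id
    v
  }
  bidx <- which(reg$role[seq_len(n)] %in% c("founder", "breeder"))
  breeder_genotypes <- geno_matrix(dosage(bidx), map)
  response_truth <- geno_matrix(dosage(resp_idx), map)

  # --- response phenotypes: all traits + fixed effects ---
  set.seed(derive_seed(cfg$seed, 3L))
  k <- length(resp_idx)
  U <- reg$u[resp_idx, , drop = FALSE]
  gsel <- reg$gsel[resp_idx]
  sexv <- reg$sex[resp_idx]
  # contemporary groups (birth-week/room batches) mix the two lines, as in
  # the real design where both lines are raised and tested together
  cg <- paste0("G", reg$gen[resp_idx], "_b", sample(1:2, k, TRUE))
  sex_eff <- stats::rnorm(Tn, sd = cfg$sex_effect_sd)
  cg_levels <- sort(unique(cg))
  cg_eff <- matrix(stats::rnorm(length(cg_levels) * Tn, sd = cfg$cg_effect_sd),
                   length(cg_levels), Tn, dimnames = list(cg_levels, NULL))
  Y <- matrix(NA_real_, k, Tn, dimnames = list(ids[resp_idx], tr$trait))
  for (t in seq_len(Tn)) {
    qt <- which(qtl_trait == tr$trait[t] & tr$trait[t] != sel_trait)
    qv <- if (length(qt)) {
      dos <- reg$H1[resp_idx, qtl_snp[qt], drop = FALSE] +
        reg$H2[resp_idx, qtl_snp[qt], drop = FALSE]
      drop(dos %*% eff[qt])
    } else 0
    if (t == 1L) {
      yt <- reg$ysel[resp_idx]   # genetic value + residual, drawn at creation
    } else {
      g_t <- c_t[t] * gsel + sqrt(wvar[t]) * U[, t] + qv
      yt <- g_t + stats::rnorm(k, sd = sqrt(max(1 - tr$h2[t], 0)))
    }
    Y[, t] <- yt + sex_eff[t] * (sexv == "M") + cg_eff[cg, t]
  }
  phen <- data.frame(id = ids[resp_idx], line = reg$line[resp_idx],
                     generation = reg$gen[resp_idx], sex = sexv, cg = cg,
                     stringsAsFactors = FALSE)
  phen <- cbind(phen, as.data.frame(Y))
  rownames(phen) <- NULL

  bph <- data.frame(id = ids[bidx], line = reg$line[bidx],
                    generation = reg$gen[bidx], sex = reg$sex[bidx],
                    stringsAsFactors = FALSE)
  bph[[sel_trait]] <- reg$ysel[bidx]

  structure(list(pedigree = ped,
                 breeder_genotypes = breeder_genotypes,
                 snp_map = map,
                 phenotypes = phen,
                 breeder_phenotypes = bph,
                 true_qtl = true_qtl,
                 response_truth = response_truth,
                 config = cfg),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("sim_output: %d pedigree rows, %d breeders x %d SNPs, %d response animals, %d QTL\n",
              nrow(x$pedigree), nrow(x$breeder_genotypes$values),
              ncol(x$breeder_genotypes$values), nrow(x$phenotypes),
              nrow(x$true_qtl)))
  invisible(x)
}

#' Simulate the breeding-design pedigree only
#'
#' Lightweight companion to [simulate_experiment()]: same mating design (F0
#' founder pairs, two lines, truncation replaced by random sire choice, dams
#' at random), but no genotypes or phenotypes. Used for purely pedigree-based
#' quantities such as the accumulation of inbreeding.
#'
#' @param n_founder_matings,n_tested_males,n_selected_sires,n_dams,n_generations
#'   design counts, defaulting to the experiment's values.
#' @param response_per_gen response animals per line per generation.
#' @param seed integer seed.
#' @return pedigree data.frame (id, sire, dam, sex, line, generation, role).
#' @export
simulate_pedigree <- function(n_founder_matings = 30, n_tested_males = 96,
                              n_selected_sires = 6, n_dams = 40,
                              n_generations = 9, response_per_gen = 40,
                              seed = 1L) {
  set.seed(derive_seed(seed, 77L))
  id_n <- 0L
  rows <- list()
  newid <- function(k) sprintf("P%05d", id_n + seq_len(k))
  emit <- function(ids, sire, dam, sex, line, gen, role) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = ids, sire = sire, dam = dam, sex = sex, line = line,
      generation = gen, role = role, stringsAsFactors = FALSE)
    id_n <<- id_n + length(ids)
  }
  f0s <- newid(n_founder_matings)
  emit(f0s, NA, NA, "M", NA, -1L, "founder")
  f0d <- newid(n_founder_matings)
  emit(f0d, NA, NA, "F", NA, -1L, "founder")
  lines <- c("HRFI", "LRFI")
  # G0: males and females from the founder litters, split across lines
  sires <- dams <- list()
  for (li in 1:2) {
    k <- sample.int(n_founder_matings, n_selected_sires, TRUE)
    s <- newid(n_selected_sires)
    emit(s, f0s[k], f0d[k], "M", lines[li], 0L, "breeder")
    k <- sample.int(n_founder_matings, n_dams, TRUE)
    d <- newid(n_dams)
    emit(d, f0s[k], f0d[k], "F", lines[li], 0L, "breeder")
    sires[[lines[li]]] <- s
    dams[[lines[li]]] <- d
  }
  for (g in seq_len(n_generations)) {
    for (ln in lines) {
      sire_of_dam <- sample(rep_len(sires[[ln]], n_dams))
      dvec <- dams[[ln]]
      if (response_per_gen > 0) {
        lit <- sample.int(n_dams, response_per_gen, TRUE)
        rids <- newid(response_per_gen)
        emit(rids, sire_of_dam[lit], dvec[lit],
             rep_len(c("F", "M"), response_per_gen), ln, g, "response")
      }
      if (g < n_generations) {
        # random sire choice stands in for phenotypic truncation
        lit <- sample.int(n_dams, n_selected_sires, TRUE)
        s <- newid(n_selected_sires)
        emit(s, sire_of_dam[lit], dvec[lit], "M", ln, g, "breeder")
        lit <- sample.int(n_dams, n_dams, TRUE)
        d <- newid(n_dams)
        emit(d, sire_of_dam[lit], dvec[lit], "F", ln, g, "breeder")
        sires[[ln]] <- s
        dams[[ln]] <- d
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
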