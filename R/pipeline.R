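#' Run the full analysis pipeline
#'
#' End-to-end orchestration over a simulated (or loaded) experiment:
#' genotype QC on breeders, parental-average genotype prediction for
#' response animals, fixed-effect adjustment of phenotypes, pedigree
#' relationship matrices, the three mixed-model association analyses
#' (global and per line) with genomic control, effective-test Bonferroni
#' thresholds, QTL-window/region assembly with SNP-QTL tags, cross-analysis
#' comparison, and allele-frequency trajectory classification of the
#' SNP-QTL. Deterministic given its inputs: re-running on the same
#' `sim_output` reproduces the summary byte for byte.
#'
#' Stage outputs are plain files (TSV/JSON) when `out_dir` is given, so any
#' stage can be re-run or swapped against external tools.
#'
#' @param sim a `sim_output` from [simulate_experiment()], or a list with
#'   elements `pedigree`, `breeder_genotypes`, `phenotypes` (and optionally
#'   `config`).
#' @param traits trait columns to analyse (default: all trait columns of
#'   the phenotype table).
#' @param analyses subset of `c("global", "HRFI", "LRFI")`.
#' @param model_spec fixed-effect columns for [adjust_phenotypes()]
#'   (default: `sex` and `cg` where present).
#' @param genomewide_mlog10 significance threshold; `NULL` (default)
#'   computes it from the effective number of independent tests.
#' @param suggestive_mlog10 suggestive threshold (default 3).
#' @param variance_kept,alpha threshold parameters
#'   (see [significance_thresholds()]).
#' @param line_differences per-trait genetic line differences (sigma_g) for
#'   the trait evolution summary; defaults to [divsel_trait_table()] values
#'   where trait names match.
#' @param qc run [qc_filter()] on the breeder genotypes first.
#' @param out_dir optional output directory for per-stage TSV/JSON files.
#' @return a `divsel_run` list: `qc_report`, `thresholds`, `assoc` (nested
#'   by analysis then trait), `regions` (by analysis), `comparison`,
#'   `trajectories`, `trait_summary`, and a machine-readable `summary`.
#' @export
run_all <- function(sim, traits = NULL,
                    analyses = c("global", "HRFI", "LRFI"),
                    model_spec = NULL, genomewide_mlog10 = NULL,
                    suggestive_mlog10 = 3, variance_kept = 0.996,
                    alpha = 0.05, line_differences = NULL, qc = TRUE,
                    out_dir = NULL) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  ped <- sim$pedigree
  phen <- sim$phenotypes
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage `%s` failed: %s", name, conditionMessage(e)))
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  save_tsv <- function(df, name) {
    if (!is.null(out_dir))
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }

  # --- genotype QC on breeders ---
  geno <- sim$breeder_genotypes
  qc_report <- NULL
  if (qc) {
    q <- stage("qc", qc_filter(geno))
    geno <- q$genotypes
    qc_report <- q$report
  }

  # --- predicted genotypes for response animals ---
  avg <- stage("predict_genotypes", predict_average_genotypes(geno, ped))

  # --- phenotype adjustment ---
  meta_cols <- c("id", "line", "generation", "sex", "cg")
  if (is.null(traits)) traits <- setdiff(names(phen), meta_cols)
  if (is.null(model_spec)) model_spec <- intersect(c("sex", "cg"), names(phen))
  adj <- stage("adjust_phenotypes", adjust_phenotypes(phen, traits, model_spec))

  # --- significance thresholds ---
  thr <- stage("thresholds",
               significance_thresholds(geno, variance_kept, alpha,
                                       suggestive_mlog10))
  gw <- genomewide_mlog10 %||% thr$genomewide_mlog10_1dp

  # --- association per analysis and trait ---
  ids_all <- intersect(adj$id, rownames(avg$values))
  line_of <- ped$line[match(ids_all, ped$id)]
  subset_ids <- list(global = ids_all,
                     HRFI = ids_all[!is.na(line_of) & line_of == "HRFI"],
                     LRFI = ids_all[!is.na(line_of) & line_of == "LRFI"])
  assoc <- list(); region_sets <- list()
  for (a in analyses) {
    ids <- subset_ids[[a]]
    A <- stage(paste0("A_matrix_", a), build_a_matrix(ped, ids))
    eig <- NULL
    assoc[[a]] <- list()
    windows <- NULL
    for (tr in traits) {
      y <- stats::setNames(adj[[tr]], adj$id)[ids]
      y <- y[!is.na(y)]
      if (is.null(eig) || !identical(eig$ids, names(y))) {
        Ay <- A[names(y), names(y)]
        ed <- eigen(Ay, symmetric = TRUE)
        eig <- list(ids = names(y), values = pmax(ed$values, 0),
                    vectors = ed$vectors)
      }
      res <- stage(paste("assoc", a, tr),
                   assoc_scan(y, avg, A, eig = eig))
      assoc[[a]][[tr]] <- res
      save_tsv(res, sprintf("assoc_%s_%s.tsv", a, tr))
      w <- make_windows(res, gw, trait = tr, analysis = a)
      windows <- if (is.null(windows)) w else rbind(windows, w)
    }
    region_sets[[a]] <- fuse_regions(windows)
    save_tsv(region_sets[[a]]$regions, sprintf("regions_%s.tsv", a))
    save_tsv(region_sets[[a]]$snp_qtl, sprintf("snp_qtl_%s.tsv", a))
  }

  # --- cross-analysis comparison ---
  comparison <- stage("compare",
                      cross_analysis_compare(region_sets, assoc, gw,
                                             suggestive_mlog10))
  if (!is.null(comparison$overlap)) save_tsv(comparison$overlap, "region_overlap.tsv")

  # --- trajectories of the SNP-QTL ---
  all_sq <- do.call(rbind, lapply(analyses, function(a) region_sets[[a]]$snp_qtl))
  trajectories <- NULL; trait_summary <- NULL
  if (!is.null(all_sq) && nrow(all_sq)) {
    usnp <- unique(all_sq$snp_id)
    tj <- stage("trajectories", fit_trajectories(avg, ped, usnp))
    trajectories <- merge(all_sq[, c("snp_id", "trait", "analysis", "region_id")],
                          tj, by = "snp_id")
    save_tsv(trajectories, "trajectories.tsv")
    if (is.null(line_differences)) {
      tt <- divsel_trait_table()
      line_differences <- stats::setNames(tt$g9_diff_sigma_g, tt$trait)
    }
    rec <- unique(trajectories[, c("snp_id", "trait", "evolution_score")])
    trait_summary <- tryCatch(
      suppressWarnings(trait_evolution_summary(rec, line_differences)),
      error = function(e) NULL)
  }

  # --- summary ---
  cat_pct <- if (!is.null(trajectories)) {
    u <- unique(trajectories[, c("snp_id", "category")])
    tb <- table(factor(u$category, levels = c("no_change", "co_selected",
                                              "opposite", "one_line_only")))
    as.list(round(100 * tb / sum(tb), 1))
  } else NULL
  summary <- list(
    n_response_analysed = length(ids_all),
    n_snps_after_qc = ncol(geno$values),
    effective_tests = thr$M,
    genomewide_mlog10 = gw,
    n_regions = lapply(region_sets, function(r) nrow(r$regions)),
    n_snp_qtl = lapply(region_sets, function(r) nrow(r$snp_qtl)),
    category_percent = cat_pct,
    trait_mean_scores = if (!is.null(trait_summary))
      stats::setNames(as.list(trait_summary$per_trait$mean_score),
                      trait_summary$per_trait$trait) else NULL,
    score_difference_correlation = if (!is.null(trait_summary))
      trait_summary$correlation else NULL
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  structure(list(qc_report = qc_report, thresholds = thr, adjusted = adj,
                 avg_genotypes = avg, assoc = assoc, regions = region_sets,
                 comparison = comparison, trajectories = trajectories,
                 trait_summary = trait_summary, summary = summary),
            class = "divsel_run")
}

#' @export
print.divsel_run <- function(x, ...) {
  s <- x$summary
  cat("divergent-selection GWAS run\n")
  cat(sprintf("  %d response animals, %d SNPs after QC, threshold %.1f (%d effective tests)\n",
              s$n_response_analysed, s$n_snps_after_qc, s$genomewide_mlog10,
              s$effective_tests))
  for (a in names(s$n_regions))
    cat(sprintf("  %s: %d region(s), %d SNP-QTL\n", a, s$n_regions[[a]],
                s$n_snp_qtl[[a]]))
  if (!is.null(s$category_percent)) {
    cat("  trajectory categories (%):",
        paste(names(s$category_percent), unlist(s$category_percent),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
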