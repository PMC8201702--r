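# a minimal avg-geno + pedigree pair with chosen per-generation dosage means
traj_fixture <- function(means_by_gen, n_per_gen = 10, line = "HRFI") {
  G <- length(means_by_gen)
  ids <- sprintf("%s_g%d_%02d", line, rep(seq_len(G), each = n_per_gen),
                 rep(seq_len(n_per_gen), G))
  v <- matrix(rep(means_by_gen, each = n_per_gen), ncol = 1,
              dimnames = list(ids, "s001"))
  ped <- data.frame(id = ids, sire = NA, dam = NA, sex = "F", line = line,
                    generation = rep(seq_len(G), each = n_per_gen),
                    role = "response", stringsAsFactors = FALSE)
  g <- toy_geno(v)
  g$certainty <- matrix(2L, nrow(v), 1, dimnames = dimnames(v))
  class(g) <- c("avg_geno", "geno_matrix")
  list(avg = g, ped = ped)
}

test_that("cumulative frequencies pool generations one at a time", {
  fx <- traj_fixture(c(0.8, 1.2, 1.0))
  f <- cumulative_frequencies(fx$avg, fx$ped, "s001", "HRFI")
  expect_equal(unname(f), c(0.4, 0.5, 0.5))
  # constant dosage 1 everywhere -> all 0.5
  fx2 <- traj_fixture(rep(1, 5))
  expect_equal(unname(cumulative_frequencies(fx2$avg, fx2$ped, "s001", "HRFI")),
               rep(0.5, 5))
  # hand-built toy: per-generation dosage means 0.4, 0.6, 0.8
  fx3 <- traj_fixture(c(0.4, 0.6, 0.8))
  expect_equal(unname(cumulative_frequencies(fx3$avg, fx3$ped, "s001", "HRFI")),
               c(0.2, 0.25, 0.3))
  # the final cumulative value equals the plain frequency over all animals
  expect_equal(unname(f)[3],
               unname(allele_frequencies(fx$avg, fx$ped$id)))
  expect_error(cumulative_frequencies(fx$avg, fx$ped, "s001", "LRFI"),
               "no response animals")
})

test_that("a missing generation is reported as a gap", {
  fx <- traj_fixture(c(0.8, 1.2, 1.0))
  ped <- fx$ped
  ped$generation[ped$generation == 2] <- 3
  keep <- !duplicated(paste(ped$id))
  expect_error(cumulative_frequencies(fx$avg, ped, "s001", "HRFI"),
               "generation")
})

test_that("slope test handles exact, flat and noisy trajectories", {
  g <- 1:9
  flat <- slope_test(rep(0.3, 9), g)
  expect_equal(flat$slope, 0)
  expect_equal(flat$wald_p, 1)
  expect_false(flat$significant)
  exact <- slope_test(0.1 + 0.024 * g, g)
  expect_equal(exact$slope, 0.024, tolerance = 1e-12)
  expect_lt(exact$wald_p, 1e-10)
  noisy <- slope_test(0.1 + 0.024 * g + rep_len(c(0.01, -0.01), 9), g)
  expect_equal(noisy$slope, 0.024, tolerance = 0.01)
  expect_error(slope_test(c(0.1, 0.2)), "3 points")
  # normal reference gives smaller p than the t reference
  nref <- slope_test(0.1 + 0.02 * g + rnorm(9, sd = 0.01), g,
                     reference = "normal")
  tref <- slope_test(0.1 + 0.02 * g + rnorm(9, sd = 0.01), g)
  expect_true(is.finite(nref$wald_p) && is.finite(tref$wald_p))
})

test_that("cumulative drift trajectories reject above the nominal rate", {
  # cumulative means are autocorrelated, so the slope test under pure drift
  # rejects more often than 5%; the rate is measured, not assumed
  set.seed(15)
  n_snp <- 300
  rej <- logical(n_snp)
  for (i in seq_len(n_snp)) {
    f <- 0.5
    traj <- numeric(9)
    for (gg in 1:9) {
      f <- rbinom(1, 80, f) / 80
      traj[gg] <- f
    }
    ctraj <- cumsum(traj) / seq_len(9)
    rej[i] <- slope_test(ctraj, 1:9)$significant
  }
  expect_gt(mean(rej), 0.05)
  expect_lt(mean(rej), 0.95)
})

test_that("evolution classification follows the four-way rule", {
  sig <- function(s) list(slope = s, se = abs(s) / 10, wald_p = 0.001,
                          significant = TRUE)
  ns <- function(s) list(slope = s, se = abs(s), wald_p = 0.6,
                         significant = FALSE)
  co <- classify_evolution(sig(0.02), sig(0.015))
  expect_equal(co$category, "co_selected")
  expect_equal(co$evolution_score, 9 * 0.035)
  op <- classify_evolution(sig(0.02), sig(-0.02))
  expect_equal(op$category, "opposite")
  expect_equal(op$evolution_score, 0.36)
  nc <- classify_evolution(ns(0.001), ns(0.002))
  expect_equal(nc$category, "no_change")
  expect_equal(nc$evolution_score, 0)
  ol <- classify_evolution(sig(0.03), ns(0.001))
  expect_equal(ol$category, "one_line_only")
  expect_equal(ol$which_line, "HRFI")
  expect_equal(ol$evolution_score, 9 * 0.03)
})

test_that("categories partition and score zero only for no_change", {
  set.seed(20)
  cats <- character(200)
  for (i in 1:200) {
    mk <- function() {
      s <- rnorm(1, 0, 0.02)
      list(slope = s, se = abs(s) + 0.001,
           wald_p = p <- runif(1), significant = p < 0.05)
    }
    cl <- classify_evolution(mk(), mk())
    cats[i] <- cl$category
    expect_equal(cl$evolution_score == 0, cl$category == "no_change")
  }
  expect_true(all(cats %in% c("no_change", "co_selected", "opposite",
                              "one_line_only")))
})

test_that("trait summary averages scores and correlates with responses", {
  rec <- data.frame(trait = c("A", "A", "B"),
                    evolution_score = c(0.05, 0.15, 0.3))
  s <- trait_evolution_summary(rec, c(A = 1, B = 3))
  expect_equal(s$per_trait$mean_score, c(0.1, 0.3))
  expect_equal(s$correlation, 1.0)
  # zero variance in scores: undefined correlation with a warning
  rec2 <- data.frame(trait = c("A", "B"), evolution_score = c(0.2, 0.2))
  expect_warning(s2 <- trait_evolution_summary(rec2, c(A = 1, B = 3)),
                 "undefined")
  expect_true(is.na(s2$correlation))
  # traits without a supplied difference are omitted with a log message
  expect_message(suppressWarnings(trait_evolution_summary(rec, c(A = 1))),
                 "omitted")
})

test_that("drift SD closed form matches its Monte-Carlo companion", {
  expect_equal(drift_sd(0.5, 40, 0), 0)
  expect_equal(round(drift_sd(0.5, 40, 9), 3), 0.164)
  sim <- drift_sim(0.25, 40, 9, n_rep = 1e5, seed = 2)
  cf <- drift_sd(0.25, 40, 9)
  se <- cf / sqrt(2 * (1e5 - 1))   # SE of an SD estimate
  expect_lt(abs(sim$sd - cf), 3 * se + 0.002)
  expect_error(drift_sd(0, 40, 9), "p0")
})

test_that("G1 line differences behave on fixtures and neutral simulations", {
  fxH <- traj_fixture(c(1.4, 1), line = "HRFI")
  fxL <- traj_fixture(c(0.9, 1), line = "LRFI")
  avg <- fxH$avg
  avg$values <- rbind(fxH$avg$values, fxL$avg$values)
  avg$certainty <- rbind(fxH$avg$certainty, fxL$avg$certainty)
  ped <- rbind(fxH$ped, fxL$ped)
  expect_equal(unname(g1_line_difference(avg, ped, "s001")), 0.25)
  # identical cohorts: zero difference
  fxL2 <- traj_fixture(c(1.4, 1), line = "LRFI")
  avg2 <- fxH$avg
  avg2$values <- rbind(fxH$avg$values, fxL2$avg$values)
  ped2 <- rbind(fxH$ped, fxL2$ped)
  expect_equal(unname(g1_line_difference(avg2, ped2, "s001")), 0)
  # neutral SNPs of a simulated design mostly differ by less than 0.1 at G1
  sim <- cached_sim()
  avg3 <- suppressMessages(predict_average_genotypes(sim$breeder_genotypes,
                                                     sim$pedigree))
  neut <- setdiff(sim$snp_map$snp_id, sim$true_qtl$snp_id)
  d <- g1_line_difference(avg3, sim$pedigree, neut)
  expect_gt(mean(d < 0.1), 0.5)
})

test_that("a strongly selected QTL is classified opposite with a high score", {
  sim <- cached_sim()
  avg <- suppressMessages(predict_average_genotypes(sim$breeder_genotypes,
                                                    sim$pedigree))
  tj <- fit_trajectories(avg, sim$pedigree, sim$true_qtl$snp_id)
  expect_equal(tj$category, "opposite")
  expect_gt(tj$evolution_score, 0.1)
})
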