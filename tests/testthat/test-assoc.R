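# random LMM instance on a random pedigree: phenotype with polygenic signal
random_instance <- function(n, seed, m = 3) {
  set.seed(seed)
  ped <- random_pedigree(n, n_founders = max(4, n %/% 5), seed = seed)
  A <- build_a_matrix(ped)
  A <- A[ped$id, ped$id]   # align to pedigree order
  L <- chol(A + diag(1e-8, n))
  y <- drop(crossprod(L, rnorm(n))) + rnorm(n)
  names(y) <- ped$id
  v <- matrix(rbinom(n * m, 2, runif(m, 0.2, 0.8)), n, m)
  storage.mode(v) <- "double"
  rownames(v) <- ped$id
  list(ped = ped, A = A, y = y, geno = toy_geno(v))
}

test_that("marker scan equals the dense-V GLS oracle", {
  inst <- random_instance(12, seed = 31)
  nf <- fit_null_lambda(inst$y, inst$A)
  res <- score_markers(inst$y, inst$geno, null_fit = nf, A = inst$A)
  for (j in seq_len(3)) {
    o <- dense_gls(inst$y, inst$geno$values[names(inst$y), j], inst$A,
                   nf$lambda)
    expect_equal(res$beta[j], o$beta, tolerance = 1e-8)
    expect_equal(res$se[j], o$se, tolerance = 1e-8)
    expect_equal(res$chi2_raw[j], o$chi2, tolerance = 1e-8)
  }
})

test_that("with A = I and lambda at zero the scan reduces to OLS", {
  set.seed(5)
  n <- 40
  y <- setNames(rnorm(n), sprintf("i%03d", 1:n))
  A <- diag(n); dimnames(A) <- list(names(y), names(y))
  v <- matrix(rbinom(n * 2, 2, 0.5), n, 2,
              dimnames = list(names(y), NULL))
  storage.mode(v) <- "double"
  g <- toy_geno(v)
  expect_warning(nf <- fit_null_lambda(y, A), "flat")
  expect_true(nf$boundary)
  res <- suppressMessages(score_markers(y, g, null_fit = nf, A = A))
  for (j in 1:2) {
    f <- summary(lm(y ~ v[, j]))$coefficients
    expect_equal(res$beta[j], f[2, 1], tolerance = 1e-6)
    expect_equal(res$se[j], f[2, 2], tolerance = 1e-6)
  }
})

test_that("degenerate phenotypes and monomorphic markers are handled", {
  inst <- random_instance(20, seed = 8)
  y0 <- setNames(rep(1, 20), names(inst$y))
  expect_error(fit_null_lambda(y0, inst$A), "zero variance")
  v <- inst$geno$values
  v[, 2] <- 2   # monomorphic
  g <- toy_geno(v)
  nf <- fit_null_lambda(inst$y, inst$A)
  expect_message(res <- score_markers(inst$y, g, null_fit = nf, A = inst$A),
                 "monomorphic")
  expect_true(is.na(res$beta[2]))
  expect_false(anyNA(res$beta[-2]))
})

test_that("markers with missing dosages use the dense fallback", {
  inst <- random_instance(25, seed = 12)
  v <- inst$geno$values
  v[1:3, 1] <- NA
  g <- toy_geno(v)
  nf <- fit_null_lambda(inst$y, inst$A)
  res <- score_markers(inst$y, g, null_fit = nf, A = inst$A)
  ok <- !is.na(v[, 1])
  o <- dense_gls(inst$y[ok], v[ok, 1], inst$A[ok, ok], nf$lambda)
  expect_equal(res$beta[1], o$beta, tolerance = 1e-8)
  expect_equal(res$n[1], sum(ok))
})

test_that("variance-ratio estimation recovers a unit ratio on deep pedigrees", {
  ped <- simulate_pedigree(n_dams = 15, n_generations = 5,
                           response_per_gen = 25, seed = 4)
  ids <- ped$id[ped$role == "response"]
  A <- build_a_matrix(ped, ids)
  L <- chol(A + diag(1e-8, nrow(A)))
  lam <- sapply(1:20, function(s) {
    set.seed(s)
    y <- setNames(drop(crossprod(L, rnorm(length(ids)))) + rnorm(length(ids)),
                  ids)
    fit_null_lambda(y, A)$lambda
  })
  expect_gte(median(lam), 0.6)
  expect_lte(median(lam), 1.6)
})

test_that("type-I error is nominal when the marker is unlinked to y", {
  # 2000 permutations of one dosage vector act as 2000 null markers
  set.seed(77)
  inst <- random_instance(60, seed = 19, m = 1)
  x <- inst$geno$values[, 1]
  perm <- sapply(1:2000, function(i) sample(x))
  rownames(perm) <- rownames(inst$geno$values)
  g <- toy_geno(perm, pos = seq_len(2000) * 100L)
  nf <- fit_null_lambda(inst$y, inst$A)
  res <- suppressMessages(score_markers(inst$y, g, null_fit = nf, A = inst$A))
  rate <- mean(res$p_raw < 0.05, na.rm = TRUE)
  half <- 3 * sqrt(0.05 * 0.95 / 2000)
  expect_gt(rate, 0.05 - half)
  expect_lt(rate, 0.05 + half)
})

test_that("genomic control estimates inflation and rescales", {
  m <- 2000
  q <- qchisq((seq_len(m) - 0.5) / m, df = 1)
  expect_equal(genomic_control(q)$inflation_factor, 1.0, tolerance = 1e-12)
  gc2 <- genomic_control(2 * q)
  expect_equal(gc2$inflation_factor, 2.0, tolerance = 1e-12)
  expect_equal(gc2$chi2_gc, q, tolerance = 1e-12)
  set.seed(10)
  draws <- rchisq(1e4, df = 1)
  lam <- genomic_control(draws)$inflation_factor
  expect_gt(lam, 0.95); expect_lt(lam, 1.05)
  lam_med <- genomic_control(draws, method = "median")$inflation_factor
  expect_gt(lam_med, 0.9); expect_lt(lam_med, 1.1)
  expect_equal(genomic_control(0.5 * q, floor_one = TRUE)$inflation_factor, 1)
})

test_that("qq data pairs ranked observations with uniform quantiles", {
  qd <- qq_data(c(0.5, 0.1, 0.9, 0.01))
  expect_equal(qd$expected_mlog10, -log10(c(0.125, 0.375, 0.625, 0.875)))
  expect_equal(qd$observed_mlog10, -log10(c(0.01, 0.1, 0.5, 0.9)))
  expect_true(all(qq_data(rep(1, 5))$observed_mlog10 == 0))
  expect_error(qq_data(c(0.5, 0)), "0, 1")
})

test_that("null simulations give inflation factors in a plausible band", {
  lams <- sapply(1:8, function(s) {
    cfg <- sim_config(n_chromosomes = 2, n_snps_per_chrom = 50,
                      n_tested_males = 20, n_tested_males_g0 = 26,
                      n_selected_sires = 4, n_dams = 12, n_generations = 6,
                      response_counts = rep(40, 6),
                      traits = divsel_trait_table()[1, , drop = FALSE],
                      n_qtl = 0, seed = 100 + s)
    sim <- simulate_experiment(cfg)
    ped <- sim$pedigree
    avg <- suppressMessages(predict_average_genotypes(sim$breeder_genotypes, ped))
    adj <- adjust_phenotypes(sim$phenotypes, "RFI", c("sex", "cg"))
    ids <- intersect(adj$id, rownames(avg$values))
    A <- build_a_matrix(ped, ids)
    y <- setNames(adj$RFI, adj$id)[ids]
    res <- suppressMessages(assoc_scan(y, avg, A))
    attr(res, "inflation_factor")
  })
  expect_gt(mean(lams), 0.9)
  expect_lt(mean(lams), 1.2)
})
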