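test_that("HWE exact p-values match a direct enumeration oracle", {
  cases <- list(c(5, 10, 5), c(0, 20, 0), c(12, 2, 6), c(3, 3, 3),
                c(0, 1, 19), c(10, 0, 10))
  for (cs in cases) {
    expect_equal(hwe_exact_p(cs[1], cs[2], cs[3]),
                 hwe_enum_p(cs[1], cs[2], cs[3]), tolerance = 1e-10)
  }
  # 1000 heterozygotes and no homozygote: extreme heterozygote excess
  expect_lt(hwe_exact_p(0, 1000, 0), 1e-10)
  # equilibrium counts are not rejected
  expect_gt(hwe_exact_p(250, 500, 250), 0.05)
})

test_that("clean genotypes pass quality control untouched", {
  set.seed(4)
  v <- matrix(rbinom(200 * 30, 2, 0.3), 200, 30)
  storage.mode(v) <- "double"
  g <- toy_geno(v)
  out <- qc_filter(g)
  expect_identical(out$genotypes$values, g$values)
  expect_equal(nrow(out$report$removed_snps), 0)
  expect_equal(nrow(out$report$removed_individuals), 0)
})

test_that("qc filters apply in order with recorded reasons", {
  set.seed(8)
  n <- 500; m <- 25
  v <- matrix(rbinom(n * m, 2, 0.4), n, m)
  storage.mode(v) <- "double"
  # snp 1: MAF 0.5% but call frequency fine (4% missing)
  v[, 1] <- 0
  v[sample(n, 5), 1] <- 1          # freq 5/1000 = 0.005
  v[sample(n, 0.04 * n), 1] <- NA
  # snp 2: everyone heterozygous -> HWE failure
  v[, 2] <- 1
  # snp 3: call frequency 90% < 95%
  v[sample(n, 0.10 * n), 3] <- NA
  # individual 1: call rate far below 90%
  v[1, ] <- NA
  v[1, 1:2] <- 2
  g <- toy_geno(v, chr = c(rep(1, m - 1), "X"))
  out <- qc_filter(g)
  rs <- out$report$removed_snps
  expect_equal(rs$reason[rs$snp_id == "s025"], "unmapped_or_sex")
  expect_equal(rs$reason[rs$snp_id == "s003"], "call_frequency")
  expect_equal(rs$reason[rs$snp_id == "s001"], "maf")
  expect_equal(rs$reason[rs$snp_id == "s002"], "hwe")
  expect_equal(out$report$removed_individuals$id, "i001")
  expect_equal(out$report$removed_individuals$reason, "call_rate")
  # accounting: removals sum to before - after
  expect_equal(nrow(rs), ncol(g$values) - out$report$n_snps_kept)
  # idempotence
  again <- qc_filter(out$genotypes)
  expect_equal(nrow(again$report$removed_snps), 0)
  expect_equal(nrow(again$report$removed_individuals), 0)
})

test_that("qc errors when a dimension is exhausted", {
  v <- matrix(1, 50, 3)   # all het: HWE kills every snp
  storage.mode(v) <- "double"
  expect_error(qc_filter(toy_geno(v)), "every SNP")
})

test_that("parental averages follow the mating table with certainty classes", {
  bre <- toy_geno(rbind(p1 = c(0, 1, 0, 1, 2), p2 = c(0, 2, 2, 1, 2)))
  ped <- data.frame(id = c("p1", "p2", "k1", "k2", "k3"),
                    sire = c(NA, NA, "p1", "p1", "p1"),
                    dam = c(NA, NA, "p2", "p2", "zz"),
                    role = c("breeder", "breeder", "response", "response",
                             "response"),
                    stringsAsFactors = FALSE)
  expect_message(avg <- predict_average_genotypes(bre, ped), "excluded 1")
  expect_identical(attr(avg, "excluded"), "k3")
  # full sibs share identical predicted rows
  expect_identical(avg$values["k1", ], avg$values["k2", ])
  # (0,0)->0 certain; (1,2)->1.5 uncertain; (0,2)->1 certain; (1,1)->1 half;
  # (2,2)->2 certain
  expect_equal(unname(avg$values["k1", ]), c(0, 1.5, 1, 1, 2))
  expect_equal(unname(avg$certainty["k1", ]), c(2L, 0L, 2L, 1L, 2L))
})

test_that("missing parental calls yield missing predicted cells", {
  bre <- toy_geno(rbind(p1 = c(0, NA), p2 = c(2, 1)))
  ped <- data.frame(id = "k", sire = "p1", dam = "p2", role = "response",
                    stringsAsFactors = FALSE)
  avg <- predict_average_genotypes(bre, ped)
  expect_equal(unname(avg$values["k", ]), c(1, NA))
  expect_equal(unname(avg$certainty["k", ]), c(2L, NA_integer_))
})

test_that("certainty summary uses the half-weight rule", {
  # matings: two 0x0, one 0x1, one 1x1 at a single snp
  bre <- toy_geno(cbind(s1 = c(0, 0, 0, 0, 0, 1, 1, 1)))
  rownames(bre$values) <- paste0("p", 1:8)
  ped <- data.frame(id = paste0("k", 1:4),
                    sire = c("p1", "p3", "p5", "p7"),
                    dam = c("p2", "p4", "p6", "p8"),
                    role = "response", stringsAsFactors = FALSE)
  cs <- certainty_summary(predict_average_genotypes(bre, ped))
  expect_equal(cs$per_snp$prop_certain, (2 + 0.5) / 4)
  # all parents homozygous identical -> proportion 1
  expect_equal(cs$per_individual$prop_certain[1], 1)
  # a 1x1 mating -> proportion 0.5 for that animal
  expect_equal(cs$per_individual$prop_certain[4], 0.5)
})

test_that("allele frequencies average dosages over non-missing cells", {
  g <- toy_geno(matrix(2, 4, 2))
  expect_equal(unname(allele_frequencies(g)), c(1, 1))
  g2 <- toy_geno(cbind(a = c(0, 0.5, 1, 1.5, 2)))
  expect_equal(unname(allele_frequencies(g2)), 0.5)
  g3 <- toy_geno(cbind(a = c(1.5, 1.5, 0.5, 1.0)))
  expect_equal(unname(allele_frequencies(g3)), 0.5625)
  # order invariance and duplication invariance
  ids <- rownames(g2$values)
  expect_equal(allele_frequencies(g2, rev(ids)), allele_frequencies(g2, ids))
  expect_warning(f <- allele_frequencies(toy_geno(cbind(a = c(NA_real_, NA_real_)))),
                 "no non-missing")
  expect_true(is.na(f))
})

test_that("MDS reproduces small distance structures exactly", {
  set.seed(11)
  v <- matrix(rbinom(3 * 60, 2, 0.5), 3, 60)
  storage.mode(v) <- "double"
  g <- toy_geno(v)
  res <- ibs_mds(g, n_axes = 2)
  D <- 1 - res$ibs
  Dhat <- as.matrix(dist(res$points))
  expect_lt(max(abs(D - Dhat)), 1e-9)
  # identical individuals land on identical coordinates
  v2 <- v; v2[2, ] <- v2[1, ]
  suppressWarnings(res2 <- ibs_mds(toy_geno(v2), n_axes = 1))
  expect_equal(res2$points[1, 1], res2$points[2, 1], tolerance = 1e-12)
})

test_that("first MDS axis separates diverged lines", {
  sim <- cached_sim()
  ped <- sim$pedigree
  g <- sim$breeder_genotypes
  late <- ped$id[ped$role == "breeder" & !is.na(ped$line) & ped$generation >= 6]
  res <- ibs_mds(subset_geno_for_test(g, late), n_axes = 2)
  line <- ped$line[match(rownames(res$points), ped$id)]
  x <- res$points[, 1]
  # silhouette-like check: within-line spread smaller than line separation
  expect_gt(abs(mean(x[line == "HRFI"]) - mean(x[line == "LRFI"])),
            sd(x[line == "HRFI"]) + sd(x[line == "LRFI"]))
})

test_that("PLINK text and dosage TSV round-trips preserve the data", {
  set.seed(13)
  # counted-allele frequency kept above 0.5 so the load-time "count the
  # major allele" orientation reproduces the original coding
  v <- matrix(rbinom(20 * 8, 2, 0.8), 20, 8)
  v[2, 3] <- NA
  storage.mode(v) <- "double"
  g <- toy_geno(v, chr = rep(c(1, 2), each = 4),
                pos = rep(c(100L, 2000L, 30000L, 400000L), 2))
  pre <- file.path(tempdir(), "rt")
  write_plink(g, pre)
  g2 <- read_plink(pre)
  expect_identical(dimnames(g2$values), dimnames(g$values))
  expect_equal(g2$values, g$values)
  expect_equal(g2$map$pos_bp, g$map$pos_bp)
  tsv <- file.path(tempdir(), "rt.tsv")
  write_dosage_tsv(g, tsv)
  g3 <- read_dosage_tsv(tsv, g$map)
  expect_equal(g3$values, g$values)
})
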