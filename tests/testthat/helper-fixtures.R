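# fixture builders and independent oracles shared across test files

# a geno_matrix with given dosage matrix (individuals x snps)
toy_geno <- function(values, chr = NULL, pos = NULL) {
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("i%03d", seq_len(nrow(values)))
  m <- ncol(values)
  map <- data.frame(snp_id = colnames(values),
                    chr = chr %||% rep(1L, m),
                    pos_bp = pos %||% (seq_len(m) * 1000L),
                    allele_counted = "A", allele_other = "B",
                    stringsAsFactors = FALSE)
  geno_matrix(values, map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

subset_geno_for_test <- function(g, ids = NULL, snps = NULL)
  divselgwas:::subset_geno(g, ids, snps)

# random genotypes in Hardy-Weinberg proportions
hw_geno <- function(n, m, p = 0.3, seed = 1) {
  set.seed(seed)
  v <- matrix(rbinom(n * m, 2, p), n, m)
  storage.mode(v) <- "double"
  toy_geno(v)
}

# random acyclic pedigree: founders first, later animals pick earlier parents
random_pedigree <- function(n, n_founders = 10, seed = 1) {
  set.seed(seed)
  sex <- rep_len(c("M", "F"), n)
  id <- sprintf("x%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1):n) {
    males <- which(sex[1:(i - 1)] == "M")
    females <- which(sex[1:(i - 1)] == "F")
    sire[i] <- id[sample(males, 1)]
    dam[i] <- id[sample(females, 1)]
  }
  data.frame(id = id, sire = sire, dam = dam, sex = sex,
             line = NA_character_, generation = NA_integer_,
             role = "breeder", stringsAsFactors = FALSE)
}

# gene-dropping estimate of the numerator relationship matrix:
# founder alleles are labelled and dropped through the pedigree; a_ij is
# estimated as half the sum over the four gamete pairings of the
# probability that the sampled alleles are identical by descent
gene_drop_a <- function(ped, n_rep = 20000, seed = 1) {
  set.seed(seed)
  ped <- sort_pedigree(ped)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  L1 <- matrix(0L, n, n_rep)
  L2 <- matrix(0L, n, n_rep)
  nal <- 0L
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (is.na(s)) {
      L1[i, ] <- nal + 1L
    } else {
      pick <- runif(n_rep) < 0.5
      L1[i, ] <- ifelse(pick, L1[s, ], L2[s, ])
    }
    if (is.na(d)) {
      L2[i, ] <- nal + 2L
    } else {
      pick <- runif(n_rep) < 0.5
      L2[i, ] <- ifelse(pick, L1[d, ], L2[d, ])
    }
    if (is.na(s) || is.na(d)) nal <- nal + 2L
  }
  peq <- function(X, Y) {
    M <- matrix(0, n, n)
    for (a in seq_len(nal)) M <- M + tcrossprod((X == a) * 1, (Y == a) * 1)
    M / n_rep
  }
  A <- 0.5 * (peq(L1, L1) + peq(L1, L2) + peq(L2, L1) + peq(L2, L2))
  dimnames(A) <- list(ped$id, ped$id)
  A
}

# dense-V generalized least squares of y on (1, x): the brute-force oracle
# for the eigen-rotation marker scan
dense_gls <- function(y, x, A, lambda) {
  n <- length(y)
  V <- lambda * A + diag(n)
  X <- cbind(1, x)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  cf <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% cf
  s2 <- drop(t(r) %*% Vi %*% r) / (n - 2)
  vb <- s2 * solve(XtViX)[2, 2]
  list(beta = cf[2], se = sqrt(vb), chi2 = cf[2]^2 / vb)
}

# exact Hardy-Weinberg probabilities by direct enumeration with choose();
# feasible for small samples, independent of the lgamma implementation
hwe_enum_p <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  nm <- min(2 * n_hom1 + n_het, 2 * n_hom2 + n_het)
  hets <- seq(nm %% 2, nm, by = 2)
  pr <- sapply(hets, function(h) {
    h1 <- (nm - h) / 2
    h2 <- n - h - h1
    factorial(n) / (factorial(h1) * factorial(h) * factorial(h2)) * 2^h
  })
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  sum(pr[pr <= obs + 1e-12])
}

# small but structured simulated experiment reused by several test files
cached_sim <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      cfg <- sim_config(n_chromosomes = 2, n_snps_per_chrom = 50,
                        founder_maf_range = c(0.35, 0.5),
                        n_tested_males = 40, n_tested_males_g0 = 50,
                        n_dams = 20, n_generations = 9,
                        response_counts = rep(96, 9),
                        traits = divsel_trait_table()[1:4, ],
                        n_qtl = 1, qtl_effects = 0.45, seed = 42)
      val <<- simulate_experiment(cfg)
    }
    val
  }
})
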