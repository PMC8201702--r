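#' Estimate the variance ratio of the null polygenic model
#'
#' Fits `y = 1 mu + u + e` with `u ~ N(0, A lambda tau^-1)` and
#' `e ~ N(0, I tau^-1)` by REML (default) or ML, profiling the variance
#' ratio `lambda = sigma2_u / sigma2_e` on `[1e-5, 1e5]` via the
#' eigen-decomposition of `A`. The decomposition is returned and reused for
#' every marker of the trait by [score_markers()].
#'
#' @param y named numeric vector of (adjusted) phenotypes; names must match
#'   rows of `A`.
#' @param A numerator relationship matrix over the same ids.
#' @param method REML or ML.
#' @param eig optional precomputed eigen-decomposition of `A[ids, ids]`
#'   (list with `ids`, `values`, `vectors`), reused across the traits of an
#'   analysis.
#' @return a `null_fit` list: `lambda`, `tau_inv` (residual variance),
#'   `loglik`, `boundary` flag, `ids`, and the eigen pair (`evalues`,
#'   `evectors`).
#' @export
fit_null_lambda <- function(y, A, method = c("REML", "ML"), eig = NULL) {
  method <- match.arg(method)
  if (is.null(names(y))) stopf("y must be a named vector (animal ids)")
  ids <- names(y)
  if (length(ids) < 10) stopf("need at least 10 phenotyped animals")
  if (stats::var(y) <= 0) stopf("phenotype has zero variance")
  if (!is.null(eig) && identical(eig$ids, ids)) {
    D <- eig$values
    U <- eig$vectors
  } else {
    if (is.null(A)) stopf("supply either A or a matching eig")
    if (!all(ids %in% rownames(A))) stopf("A lacks some phenotyped ids")
    A <- A[ids, ids]
    ed <- eigen(A, symmetric = TRUE)
    D <- pmax(ed$values, 0)
    U <- ed$vectors
  }
  n <- length(y)
  yt <- drop(crossprod(U, y))
  xt <- drop(crossprod(U, rep(1, n)))
  ll_fun <- function(log10l) {
    l <- 10^log10l
    w <- 1 / (l * D + 1)
    xwx <- sum(w * xt^2)
    b <- sum(w * xt * yt) / xwx
    rss <- sum(w * (yt - xt * b)^2)
    if (method == "ML") {
      s2 <- rss / n
      -0.5 * (n * log(2 * pi * s2) + sum(log(l * D + 1)) + n)
    } else {
      s2 <- rss / (n - 1)
      -0.5 * ((n - 1) * log(2 * pi * s2) + sum(log(l * D + 1)) + log(xwx) + (n - 1))
    }
  }
  grid <- seq(-5, 5, length.out = 21)
  llg <- vapply(grid, ll_fun, 0)
  if (any(!is.finite(llg))) stopf("non-finite likelihood on the search grid")
  boundary <- FALSE
  if (diff(range(llg)) < 1e-8) {
    warnf("likelihood is flat in lambda (A has no usable structure); returning the lower bound")
    lopt <- -5
    boundary <- TRUE
  } else {
    best <- grid[which.max(llg)]
    lo <- max(-5, best - 1); hi <- min(5, best + 1)
    opt <- stats::optimize(ll_fun, c(lo, hi), maximum = TRUE, tol = 1e-8)
    lopt <- opt$maximum
    if (ll_fun(-5) >= opt$objective) { lopt <- -5; boundary <- TRUE }
    if (ll_fun(5) >= opt$objective) { lopt <- 5; boundary <- TRUE }
    if (min(abs(lopt - c(-5, 5))) < 1e-3) boundary <- TRUE
  }
  lambda <- 10^lopt
  w <- 1 / (lambda * D + 1)
  xwx <- sum(w * xt^2)
  b <- sum(w * xt * yt) / xwx
  rss <- sum(w * (yt - xt * b)^2)
  if (boundary) message("lambda estimate at the boundary of the search interval")
  structure(list(lambda = lambda,
                 tau_inv = rss / (n - 1),
                 loglik = ll_fun(lopt),
                 boundary = boundary,
                 method = method,
                 ids = ids, evalues = D, evectors = U),
            class = "null_fit")
}

#' Single-marker mixed-model association scan
#'
#' For each marker, generalized least squares of `y` on (intercept, dosage)
#' under `V = lambda A + I` (up to the residual variance, re-estimated per
#' marker), using the eigen-rotation of `A` from [fit_null_lambda()]. The
#' Wald statistic `(beta/se)^2` is referred to a 1-df chi-square.
#' Monomorphic markers (zero dosage variance among analysed animals) are
#' skipped. Markers with missing dosages fall back to a dense-V GLS on
#' complete cases.
#'
#' @param y named numeric phenotype vector.
#' @param geno [geno_matrix()] (typically parental-average dosages) covering
#'   the ids of `y`.
#' @param null_fit a `null_fit` from [fit_null_lambda()] on the same ids
#'   (order may differ), or `NULL` to fit it here.
#' @param A relationship matrix, required when `null_fit` is `NULL` or for
#'   the missing-data fallback.
#' @return data.frame (one row per marker): snp_id, chr, pos_bp, n, beta,
#'   se, chi2_raw, p_raw, mlog10p_raw; attribute `lambda`.
#' @export
score_markers <- function(y, geno, null_fit = NULL, A = NULL) {
  if (is.null(names(y))) stopf("y must be a named vector (animal ids)")
  if (is.null(null_fit)) {
    if (is.null(A)) stopf("supply either null_fit or A")
    null_fit <- fit_null_lambda(y, A)
  }
  if (!setequal(names(y), null_fit$ids)) stopf("null_fit was computed on different ids")
  ids <- null_fit$ids
  y <- y[ids]
  miss_id <- setdiff(ids, rownames(geno$values))
  if (length(miss_id)) stopf("genotypes missing for %d phenotyped animal(s)", length(miss_id))
  X <- geno$values[ids, , drop = FALSE]
  lambda <- null_fit$lambda
  n <- length(y)
  out <- data.frame(snp_id = geno$map$snp_id, chr = geno$map$chr,
                    pos_bp = geno$map$pos_bp, n = NA_integer_,
                    beta = NA_real_, se = NA_real_, chi2_raw = NA_real_,
                    stringsAsFactors = FALSE)
  complete <- !colSums(is.na(X))
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  mono <- !is.na(sds) & sds == 0
  if (any(mono))
    message(sprintf("%d monomorphic marker(s) skipped", sum(mono)))
  if (mean(mono) > 0.5)
    warnf("more than half of the markers are monomorphic in this subset")
  do_fast <- complete & !mono
  if (any(do_fast)) {
    U <- null_fit$evectors
    D <- null_fit$evalues
    w <- 1 / (lambda * D + 1)
    yt <- drop(crossprod(U, y))
    x0 <- drop(crossprod(U, rep(1, n)))
    Xt <- crossprod(U, X[, do_fast, drop = FALSE])
    a11 <- sum(w * x0^2)
    b1 <- sum(w * x0 * yt)
    yy <- sum(w * yt^2)
    a12 <- drop(crossprod(w * x0, Xt))
    a22 <- drop(crossprod(w, Xt^2))
    b2 <- drop(crossprod(w * yt, Xt))
    det <- a11 * a22 - a12^2
    beta <- (a11 * b2 - a12 * b1) / det
    mu <- (a22 * b1 - a12 * b2) / det
    rss <- pmax(yy - mu * b1 - beta * b2, 0)
    s2 <- rss / (n - 2)
    vb <- s2 * a11 / det
    out$n[do_fast] <- n
    out$beta[do_fast] <- beta
    out$se[do_fast] <- sqrt(vb)
    out$chi2_raw[do_fast] <- beta^2 / vb
  }
  slow <- which(!complete & !mono)
  if (length(slow)) {
    if (is.null(A)) stopf("markers with missing dosages need A for the dense fallback")
    A <- A[ids, ids]
    for (j in slow) {
      ok <- !is.na(X[, j])
      nj <- sum(ok)
      if (nj < 5 || stats::sd(X[ok, j]) == 0) next
      V <- lambda * A[ok, ok] + diag(nj)
      Xj <- cbind(1, X[ok, j])
      Vi_X <- solve(V, Xj)
      XtVX <- crossprod(Xj, Vi_X)
      cf <- solve(XtVX, crossprod(Vi_X, y[ok]))
      r <- y[ok] - Xj %*% cf
      s2 <- drop(crossprod(r, solve(V, r))) / (nj - 2)
      vb <- s2 * solve(XtVX)[2, 2]
      out$n[j] <- nj
      out$beta[j] <- cf[2]
      out$se[j] <- sqrt(vb)
      out$chi2_raw[j] <- cf[2]^2 / vb
    }
  }
  out$p_raw <- stats::pchisq(out$chi2_raw, 1, lower.tail = FALSE)
  out$mlog10p_raw <- mlog10_chisq1(out$chi2_raw)
  attr(out, "lambda") <- lambda
  out
}

#' Genomic control
#'
#' Estimates the inflation factor of a set of 1-df chi-square statistics
#' and divides each statistic by it. The default estimator is the slope of
#' the through-origin regression of the sorted observed statistics on the
#' theoretical chi-square(1) quantiles; `method = "median"` uses
#' `median(chi2) / 0.4549` instead. The factor is not floored at 1 unless
#' `floor_one = TRUE`.
#'
#' @param chi2 vector of raw chi-square statistics (NAs ignored).
#' @param method inflation estimator.
#' @param floor_one never deflate (factor < 1 reset to 1).
#' @return list: `inflation_factor`, `chi2_gc`, `p_gc`, `mlog10p_gc`.
#' @export
genomic_control <- function(chi2, method = c("regression", "median"),
                            floor_one = FALSE) {
  method <- match.arg(method)
  ok <- is.finite(chi2)
  m <- sum(ok)
  if (m < 100) warnf("only %d statistics; the inflation estimate will be noisy", m)
  obs <- sort(chi2[ok])
  if (method == "regression") {
    q <- stats::qchisq((seq_len(m) - 0.5) / m, df = 1)
    lam <- sum(q * obs) / sum(q^2)
  } else {
    lam <- stats::median(obs) / stats::qchisq(0.5, df = 1)
  }
  if (floor_one) lam <- max(lam, 1)
  chi2_gc <- chi2 / lam
  list(inflation_factor = lam,
       chi2_gc = chi2_gc,
       p_gc = stats::pchisq(chi2_gc, 1, lower.tail = FALSE),
       mlog10p_gc = mlog10_chisq1(chi2_gc))
}

#' Quantile-quantile data for association p-values
#'
#' @param p vector of p-values in (0, 1].
#' @return data.frame with `expected_mlog10 = -log10((i - 0.5)/m)` and
#'   `observed_mlog10` for the ranked p-values (largest pair first).
#' @export
qq_data <- function(p) {
  p <- p[is.finite(p)]
  if (any(p <= 0 | p > 1)) stopf("p-values must lie in (0, 1]")
  m <- length(p)
  sp <- sort(p)
  data.frame(expected_mlog10 = -log10((seq_len(m) - 0.5) / m),
             observed_mlog10 = -log10(sp))
}

#' One-trait, one-subset association analysis
#'
#' Convenience wrapper: null-model variance ratio, marker scan, genomic
#' control. The three line analyses (global, HRFI, LRFI) differ only in the
#' id subset passed through `y`.
#'
#' @inheritParams score_markers
#' @param A relationship matrix over (at least) the ids of `y`.
#' @param gc_method passed to [genomic_control()].
#' @param eig optional precomputed eigen-decomposition (see
#'   [fit_null_lambda()]).
#' @return `AssocResult` data.frame: marker columns plus `chi2_gc`, `p`,
#'   `mlog10p`; attributes `lambda` and `inflation_factor`.
#' @export
assoc_scan <- function(y, geno, A, gc_method = "regression", eig = NULL) {
  y <- y[!is.na(y)]
  nf <- fit_null_lambda(y, A, eig = eig)
  res <- score_markers(y, geno, null_fit = nf, A = A)
  gc <- genomic_control(res$chi2_raw, method = gc_method)
  res$chi2_gc <- gc$chi2_gc
  res$p <- gc$p_gc
  res$mlog10p <- gc$mlog10p_gc
  attr(res, "lambda") <- nf$lambda
  attr(res, "inflation_factor") <- gc$inflation_factor
  res
}
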