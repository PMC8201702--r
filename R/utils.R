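# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic substream seed derived from a master seed. Keeps results
# below .Machine$integer.max so seeds survive as.integer().
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 7919 + 12345) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.finite(x) && x >= min && x == as.integer(x)
}

# -log10(p) for an upper-tail chi-square(1) statistic, stable for huge
# statistics where pchisq() underflows.
mlog10_chisq1 <- function(chi2) {
  -stats::pchisq(chi2, df = 1, lower.tail = FALSE, log.p = TRUE) / log(10)
}
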