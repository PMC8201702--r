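#' Average metabolic body weight over the test period
#'
#' `AMBW = (BW1^1.6 - BW0^1.6) / (1.6 * (BW1 - BW0))`, the time-average of
#' metabolic body weight `BW^0.6` for linear growth between the start weight
#' `BW0` and the end weight `BW1` (kg). As `BW0 -> BW1` the value tends to
#' `BW1^0.6`.
#'
#' @param bw0,bw1 start and end body weights in kg, `bw1 > bw0 > 0`.
#'   Vectorised.
#' @return AMBW on the kg^0.6 scale.
#' @export
ambw <- function(bw0, bw1) {
  if (any(!is.finite(bw0) | !is.finite(bw1))) stopf("non-finite body weight")
  if (any(bw0 <= 0) || any(bw1 <= bw0)) stopf("need bw1 > bw0 > 0")
  (bw1^1.6 - bw0^1.6) / (1.6 * (bw1 - bw0))
}

#' Lean meat content of the carcass
#'
#' Fixed linear combination of carcass component percentages:
#' `LMC (%) = 25.08 - 1.23 backfat + 0.87 loin + 0.73 ham`.
#'
#' @param backfat_pct,loin_pct,ham_pct component weights as percentages of
#'   the half-carcass weight. Vectorised.
#' @return lean meat content in percent.
#' @export
lmc <- function(backfat_pct, loin_pct, ham_pct) {
  if (any(c(backfat_pct, loin_pct, ham_pct) < 0)) stopf("percentages must be >= 0")
  25.08 - 1.23 * backfat_pct + 0.87 * loin_pct + 0.73 * ham_pct
}

#' Residual feed intake
#'
#' `RFI = DFI - 1.48 ADG + 23.2 LMC - 99.1 AMBW`, with fixed regression
#' coefficients. The default reproduces the printed expression verbatim
#' (signs as printed); `conventional_signs = TRUE` switches to the usual
#' regression-residual sign pattern in which every production term is
#' subtracted (`DFI - 1.48 ADG - 23.2 LMC - 99.1 AMBW`), since the printed
#' signs are inconsistent with the definition of RFI as a regression
#' residual (see the methods vignette).
#'
#' @param dfi daily feed intake (g/day).
#' @param adg average daily gain (g/day).
#' @param lmc lean meat content (%).
#' @param ambw average metabolic body weight ([ambw()]).
#' @param conventional_signs use the all-minus sign pattern.
#' @return residual feed intake, same units as `dfi`. Vectorised.
#' @export
rfi <- function(dfi, adg, lmc, ambw, conventional_signs = FALSE) {
  if (any(!is.finite(c(dfi, adg, lmc, ambw)))) stopf("non-finite input")
  if (conventional_signs) {
    dfi - 1.48 * adg - 23.2 * lmc - 99.1 * ambw
  } else {
    dfi - 1.48 * adg + 23.2 * lmc - 99.1 * ambw
  }
}

#' Pre-adjust phenotypes for fixed effects
#'
#' Ordinary least-squares fit per trait of the stated fixed effects and
#' covariates; the residuals become the phenotypes used in association. The
#' full stated model is fitted for every trait (no significance-based term
#' selection); terms can be dropped per trait through `model_spec`. Animals
#' missing the trait or any model column are dropped for that trait only.
#' Aliased (rank-deficient) columns are dropped by the fitter with a
#' warning, never silently.
#'
#' @param phenos data.frame with column `id`, trait columns, and the
#'   fixed-effect/covariate columns named in `model_spec`.
#' @param traits character vector of trait column names.
#' @param model_spec either a character vector of model columns applied to
#'   every trait (categorical columns are factors, numeric columns enter as
#'   covariates), or a named list mapping trait -> character vector.
#' @return data.frame `id` + one residual column per trait (`NA` where the
#'   animal was dropped); per trait, residuals sum to ~0 over fitted
#'   animals. Attribute `n_used` records the per-trait fit size.
#' @export
adjust_phenotypes <- function(phenos, traits, model_spec) {
  if (!"id" %in% names(phenos)) stopf("phenos needs an `id` column")
  if (!all(traits %in% names(phenos)))
    stopf("missing trait column(s): %s",
          paste(setdiff(traits, names(phenos)), collapse = ", "))
  spec_for <- function(tr) {
    s <- if (is.list(model_spec)) model_spec[[tr]] %||% character(0) else model_spec
    miss <- setdiff(s, names(phenos))
    if (length(miss)) stopf("model_spec names missing column(s): %s",
                            paste(miss, collapse = ", "))
    s
  }
  out <- data.frame(id = as.character(phenos$id), stringsAsFactors = FALSE)
  n_used <- integer(0)
  for (tr in traits) {
    sp <- spec_for(tr)
    df <- phenos[, c(tr, sp), drop = FALSE]
    for (v in sp) if (!is.numeric(df[[v]])) df[[v]] <- factor(df[[v]])
    ok <- stats::complete.cases(df)
    res <- rep(NA_real_, nrow(phenos))
    if (sum(ok) >= length(sp) + 2L) {
      form <- if (length(sp)) {
        stats::reformulate(sp, response = tr)
      } else {
        stats::as.formula(paste(tr, "~ 1"))
      }
      fit <- stats::lm(form, data = df[ok, , drop = FALSE])
      if (any(is.na(stats::coef(fit))))
        warnf("aliased level(s) dropped in the fixed-effect model for %s", tr)
      res[ok] <- stats::residuals(fit)
    } else {
      warnf("trait %s: too few complete records to adjust; all NA", tr)
    }
    out[[tr]] <- res
    n_used[tr] <- sum(ok)
  }
  attr(out, "n_used") <- n_used
  out
}
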