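#' Trait panel of the divergent-selection design
#'
#' The 24 production, carcass and meat-quality traits recorded on response
#' animals, with their narrow-sense heritabilities and the realised G9
#' between-line differences (in genetic standard deviations of each trait).
#' RFI (residual feed intake) is the selection criterion. The
#' `corr_to_selected` column is the default genetic correlation to RFI used
#' by the simulator; it is derived from correlated-response theory as the
#' ratio of each trait's realised response (in sigma_g) to the RFI response,
#' capped at 0.9 (see the methods vignette).
#'
#' @return data.frame with columns `trait`, `h2`, `g9_diff_sigma_g`,
#'   `corr_to_selected`.
#' @export
divsel_trait_table <- function() {
  tab <- data.frame(
    trait = c("RFI", "DFI", "ADG", "FCR", "carcBFT",
              "a_GM", "a_GS", "b_GM", "b_GS", "L_GM", "L_GS",
              "pH24h_AD", "pH24h_GS", "pH24h_LM", "pH24h_SM",
              "WHC", "MQI", "LMCcalc", "DP",
              "Belly_W", "BF_W", "Ham_W", "Loin_W", "Shoulder_W"),
    h2 = c(0.13, 0.41, 0.50, 0.42, 0.40,
           0.29, 0.26, 0.24, 0.32, 0.20, 0.33,
           0.41, 0.39, 0.32, 0.38,
           0.04, 0.33, 0.59, 0.36,
           0.28, 0.43, 0.51, 0.54, 0.38),
    g9_diff_sigma_g = c(3.84, 2.11, 0.15, 2.46, 0.03,
                        0.38, 0.12, 0.09, 1.14, 0.38, 2.12,
                        1.39, 1.98, 1.45, 1.74,
                        0.68, 1.92, 1.31, 0.93,
                        1.90, 0.92, 0.97, 1.69, 1.11),
    stringsAsFactors = FALSE
  )
  tab$corr_to_selected <- pmin(tab$g9_diff_sigma_g / tab$g9_diff_sigma_g[1], 0.9)
  tab$corr_to_selected[1] <- 1
  tab
}
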