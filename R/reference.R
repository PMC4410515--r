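#' Published model summaries from the original urn-study reanalysis
#'
#' The regression-model comparison reported in the original urn-study
#' reanalysis that this package's pipeline reconstructs: the Bayesian model
#' MO (credence predicted by the objective posterior alone), the five
#' explanationist models adding computed explanatory-power scores of the two
#' urn hypotheses under one measure each (Popper's measure and the
#' \eqn{L_{0.5}}, \eqn{L_1}, \eqn{L_2} rescalings of Good's measure, and the
#' Schupbach-Sprenger measure), and MOAB, the model using participants'
#' judged explanatory goodness. For MOAB only AIC, \eqn{R^2}, and the
#' likelihood-ratio chi-squared against MO were reported, so its `k` and
#' `LL` are `NA`.
#'
#' These printed values serve as fixed inputs for arithmetic-consistency
#' checks ([comparison_from_summaries()]); the underlying 26-participant
#' interview data were never deposited, so the fits themselves cannot be
#' recomputed.
#'
#' @return `urn_study_models()`: data frame with columns `model`, `k`, `LL`,
#'   `AIC`, `dAIC`, `chi2`, `R2` as printed, plus MOAB's reported values.
#' @examples
#' urn_study_models()
#' @export
urn_study_models <- function() {
  data.frame(
    model = c("MO", "MOA_P_B_P", "MOA_G1_B_G1", "MOA_G2_B_G2",
              "MOA_G3_B_G3", "MOA_SS_B_SS", "MOAB"),
    k = c(3, 5, 5, 5, 5, 5, NA),
    LL = c(202.39, 222.64, 216.72, 211.27, 228.41, 208.27, NA),
    AIC = c(-398.77, -435.27, -423.43, -412.53, -446.83, -406.53, -519.64),
    dAIC = c(48.06, 11.55, 23.40, 34.29, 0.00, 40.30, NA),
    chi2 = c(NA, 40.50, 28.66, 17.76, 52.06, 11.76, 124.87),
    R2 = c(0.83, 0.85, 0.85, 0.84, 0.86, 0.84, 0.90)
  )
}

#' @rdname urn_study_models
#' @return `urn_study_coefficients()`: data frame of the reported
#'   coefficient table of the best explanationist model
#'   (intercept, O, and the two \eqn{L_2}-scored predictors), with columns
#'   `term`, `B`, `SE_B`, `beta`, `t`, `p`. The p values reported only as
#'   upper bounds ("< 0.0001") are stored as `1e-04`.
#' @examples
#' urn_study_coefficients()
#' @export
urn_study_coefficients <- function() {
  data.frame(
    term = c("Intercept", "O", "A_G3", "B_G3"),
    B = c(0.33, 0.40, 0.24, -0.13),
    SE_B = c(0.02, 0.04, 0.03, 0.03),
    beta = c(NA, 0.56, 0.30, -0.15),
    t = c(14.90, 9.72, 7.48, -3.67),
    p = c(1e-04, 1e-04, 1e-04, 2e-04)
  )
}
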