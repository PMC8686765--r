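#' Measured exchange rates of the ATPase strain panel
#'
#' Published specific growth, glucose uptake and product synthesis rates
#' (means of three biological replicates, mmol/gDW/h; growth rate 1/h) of
#' *E. coli* MG1655 carrying low- (LC), medium- (MC) or high-copy (HC)
#' ATPase expression plasmids and their empty-vector controls, under
#' anaerobic conditions with growth and under anaerobic growth arrest.
#' The `atpm` column is the ATP-maintenance flux obtained by flux analysis
#' of these rates and `atpase` the ATPase flux derived from it (reported for
#' the ATPase strains only).
#'
#' @param condition `"growth"` or `"arrest"`.
#' @return Data frame, one row per strain, with columns `strain`, `mu`,
#'   `glc`, `eth`, `ace`, `for`, `lac`, `suc`, `atpm`, `atpase` and the
#'   replicate SDs (`sd_` prefix) of the measured rates.
#' @export
atpase_exchange_rates <- function(condition = c("growth", "arrest")) {
  condition <- match.arg(condition)
  if (condition == "growth") {
    df <- data.frame(
      strain = c("WT", "WT_IPTG", "LC_control", "LC_ATPase",
                 "MC_control", "MC_ATPase", "HC_control", "HC_ATPase"),
      mu  = c(0.476, 0.449, 0.458, 0.376, 0.461, 0.197, 0.431, 0.063),
      glc = c(13.48, 12.78, 14.05, 16.38, 15.02, 17.70, 12.93, 5.13),
      eth = c(10.81, 9.99, 10.38, 13.23, 10.51, 15.63, 9.84, 2.29),
      ace = c(11.90, 10.73, 10.74, 13.23, 10.93, 14.90, 9.89, 3.28),
      "for" = c(21.88, 19.54, 20.78, 26.99, 21.21, 30.24, 20.46, 4.69),
      lac = c(0.83, 0.67, 0.89, 1.30, 0.98, 0.84, 0.83, 2.95),
      suc = c(1.77, 1.72, 1.73, 1.80, 1.85, 1.66, 1.65, 0.45),
      atpm = c(4.41, 3.27, 3.30, 14.63, 3.61, 29.06, 2.67, 6.99),
      atpase = c(NA, NA, NA, 11.33, NA, 25.45, NA, 4.32),
      sd_mu  = c(0.004, 0.007, 0.004, 0.007, 0.002, 0.003, 0.004, 0.009),
      sd_glc = c(0.04, 0.48, 0.42, 0.56, 0.15, 0.47, 1.11, 0.51),
      sd_eth = c(0.14, 0.15, 0.24, 0.33, 0.19, 0.94, 0.52, 0.51),
      sd_ace = c(0.19, 0.30, 0.23, 0.22, 0.37, 0.59, 0.24, 0.39),
      sd_for = c(0.37, 0.26, 1.07, 0.86, 0.30, 0.25, 0.66, 0.96),
      sd_lac = c(0.05, 0.05, 0.07, 0.11, 0.07, 0.34, 0.09, 0.13),
      sd_suc = c(0.02, 0.02, 0.10, 0.07, 0.05, 0.08, 0.09, 0.17),
      check.names = FALSE, stringsAsFactors = FALSE
    )
  } else {
    df <- data.frame(
      strain = c("WT", "WT_IPTG", "LC_control", "LC_ATPase",
                 "MC_control", "MC_ATPase", "HC_control", "HC_ATPase"),
      mu  = rep(0, 8),
      glc = c(1.90, 2.02, 2.34, 8.96, 2.18, 10.46, 2.95, 8.10),
      eth = c(1.43, 1.43, 1.47, 4.78, 1.43, 3.16, 1.34, 0.66),
      ace = c(1.55, 1.50, 1.58, 4.69, 1.54, 2.56, 1.43, 0.60),
      "for" = c(2.23, 2.09, 2.10, 7.65, 2.04, 4.28, 2.17, 0.42),
      lac = c(0.12, 0.22, 0.32, 5.71, 0.49, 11.31, 1.51, 13.78),
      suc = c(0.75, 0.71, 0.95, 2.20, 0.89, 1.95, 0.94, 0.35),
      atpm = c(4.16, 4.29, 4.59, 18.62, 4.63, 19.31, 5.42, 15.63),
      atpase = c(NA, NA, NA, 14.33, NA, 14.68, NA, 10.21),
      sd_mu  = rep(0, 8),
      sd_glc = c(0.11, 0.06, 0.34, 0.36, 0.06, 0.43, 0.09, 0.60),
      sd_eth = c(0.21, 0.04, 0.04, 0.35, 0.09, 0.40, 0.06, 0.14),
      sd_ace = c(0.07, 0.02, 0.04, 0.28, 0.03, 0.54, 0.06, 0.03),
      sd_for = c(0.18, 0.03, 0.10, 0.47, 0.07, 0.82, 0.12, 0.03),
      sd_lac = c(0.02, 0.04, 0.12, 0.12, 0.19, 0.54, 0.10, 0.36),
      sd_suc = c(0.03, 0.02, 0.02, 0.08, 0.06, 0.01, 0.04, 0.04),
      check.names = FALSE, stringsAsFactors = FALSE
    )
  }
  df
}

#' Measured product yields of the ATPase strain panel
#'
#' Published product yields (mol per mol glucose) matching
#' [atpase_exchange_rates()].
#'
#' @inheritParams atpase_exchange_rates
#' @return Data frame with columns `strain`, `eth`, `ace`, `for`, `lac`,
#'   `suc`.
#' @export
atpase_yields <- function(condition = c("growth", "arrest")) {
  condition <- match.arg(condition)
  if (condition == "growth") {
    data.frame(
      strain = c("WT", "WT_IPTG", "LC_control", "LC_ATPase",
                 "MC_control", "MC_ATPase", "HC_control", "HC_ATPase"),
      eth = c(0.696, 0.716, 0.678, 0.770, 0.668, 0.857, 0.655, 0.460),
      ace = c(0.753, 0.774, 0.665, 0.790, 0.666, 0.840, 0.645, 0.650),
      "for" = c(1.299, 1.309, 1.280, 1.542, 1.251, 1.572, 1.268, 0.899),
      lac = c(0.184, 0.166, 0.177, 0.161, 0.184, 0.143, 0.246, 0.570),
      suc = c(0.125, 0.130, 0.118, 0.106, 0.124, 0.085, 0.125, 0.083),
      check.names = FALSE, stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      strain = c("WT", "WT_IPTG", "LC_control", "LC_ATPase",
                 "MC_control", "MC_ATPase", "HC_control", "HC_ATPase"),
      eth = c(0.738, 0.703, 0.658, 0.497, 0.683, 0.284, 0.512, 0.076),
      ace = c(0.840, 0.758, 0.704, 0.467, 0.709, 0.259, 0.406, 0.092),
      "for" = c(1.114, 0.993, 0.915, 0.645, 0.901, 0.305, 0.520, 0.059),
      lac = c(0.063, 0.084, 0.128, 0.728, 0.221, 1.177, 0.734, 1.740),
      suc = c(0.383, 0.341, 0.413, 0.227, 0.407, 0.155, 0.289, 0.043),
      check.names = FALSE, stringsAsFactors = FALSE
    )
  }
}

#' Measured rates of the HC ATPase overexpression variants
#'
#' Published rates (anaerobic growth) for the high-copy ATPase strain and
#' its variants additionally overexpressing the genes for
#' phosphofructokinase (pfkA), pyruvate formate-lyase (pflB), both, or
#' phosphoglycerate kinase (pgk, the zero-control predicted to have no flux
#' control).
#'
#' @return Data frame, one row per variant, with columns `strain`, `mu`,
#'   `glc`, `eth`, `ace`, `for`, `lac`, `suc`, `atpm`, `atpase`.
#' @export
atpase_variant_rates <- function() {
  data.frame(
    strain = c("HC_ATPase", "HC_ATPase_pfkA", "HC_ATPase_pflB",
               "HC_ATPase_pfkA_pflB", "HC_ATPase_pgk"),
    mu  = c(0.063, 0.134, 0.079, 0.098, 0.074),
    glc = c(5.13, 7.51, 7.59, 7.87, 4.92),
    eth = c(2.29, 5.05, 5.81, 6.26, 2.12),
    ace = c(3.28, 5.56, 6.32, 6.84, 3.36),
    "for" = c(4.69, 9.32, 10.88, 11.44, 5.38),
    lac = c(2.95, 2.41, 1.18, 1.01, 2.33),
    suc = c(0.45, 1.17, 0.89, 1.07, 0.80),
    atpm = c(6.99, 9.26, 12.67, 12.97, 5.47),
    atpase = c(4.32, 6.59, 10.00, 10.30, 2.80),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}
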