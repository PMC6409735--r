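# Krogh-cylinder exchange between plasma and tumor extracellular space, and
# the extracellular balances of conjugate (nM per total tumor volume) and
# free payload (nmol).

#' Plasma-tumor exchange rate
#'
#' Sum of vascular exchange (`2*P*R_cap/R_Krogh^2`, Krogh-cylinder
#' permeability across tumor capillaries) and surface exchange
#' (`6*D/R_tumor^2`, diffusion across the tumor surface).  Surface exchange
#' dominates for small tumors; the rate decreases monotonically with tumor
#' radius toward the vascular term.
#'
#' @param P Vascular permeability, um/day.
#' @param D Diffusivity, cm^2/day.
#' @param R_cap Capillary radius, um.
#' @param R_Krogh Average half-distance between capillaries, um.
#' @param R_tumor Tumor radius, cm.
#' @return Exchange rate, 1/day.
#' @examples
#' exchange_rate(334, 0.022, 8, 75, 0.6204)  # ~1.293 /day for the conjugate
#' @export
exchange_rate <- function(P, D, R_cap, R_Krogh, R_tumor) {
  if (any(R_tumor <= 0)) stop("R_tumor must be positive")
  if (P < 0 || D < 0 || R_cap <= 0 || R_Krogh <= 0) {
    stop("exchange parameters must be non-negative (radii positive)")
  }
  2 * P * R_cap / R_Krogh^2 + 6 * D / R_tumor^2
}

#' Tumor extracellular right-hand side
#'
#' Derivatives of the tumor extracellular states and the equal-and-opposite
#' coupling fluxes applied to plasma.  The conjugate state `ADCf_ex` is a
#' concentration per total tumor volume (nM; the free interstitial
#' concentration is `ADCf_ex / eps_ADC`), the payload state `Drugf_ex` an
#' amount (nmol).  With `death_release = TRUE` the content of cells exiting
#' the last transit compartment is added back (PD-coupled mode).
#'
#' @param state Named vector with `ADCf_ex` (nM) and `Drugf_ex` (nmol).
#' @param plasma_state Named plasma state vector (see [plasma_rhs()]).
#' @param cell_state Named per-cell state vector (see [cell_rhs()]).
#' @param TV_mm3 Total tumor volume, mm^3.
#' @param TV4_mm3 Volume in the last transit compartment, mm^3.
#' @param p An [adc_params()] set.
#' @param death_release Include the dying-cell release terms?
#' @return List with `derivatives` (nM/day, nmol/day) and the plasma
#'   coupling fluxes `flux_ADC`, `flux_Drug` (nmol/day into the tumor).
#' @export
tumor_ex_rhs <- function(state, plasma_state, cell_state, TV_mm3,
                         TV4_mm3 = 0, p, death_release = FALSE) {
  TV_L <- TV_mm3 * 1e-6
  R <- radius_from_volume(TV_L)
  kexA <- exchange_rate(p$P_ADC, p$D_ADC, p$R_cap, p$R_Krogh, R)
  kexD <- exchange_rate(p$P_Drug, p$D_Drug, p$R_cap, p$R_Krogh, R)
  NC <- cells_from_volume(TV_mm3, p$cells_per_mm3)
  V1A <- p$V1_ADC * p$body_weight
  ADCf <- state[["ADCf_ex"]]; DRGf <- state[["Drugf_ex"]]
  X1 <- plasma_state[["X1_ADC"]]; C1 <- plasma_state[["C1_Drug"]]
  DAR <- plasma_state[["DAR"]]
  ADCb <- cell_state[["ADCb_cell"]]; DFC <- cell_state[["Drugf_cell"]]

  flux_ADC <- (X1 / V1A - ADCf / p$eps_ADC) * TV_L * kexA
  flux_Drug <- (C1 - DRGf / (TV_L * p$eps_Drug)) * TV_L * kexD
  bind <- p$Kon_ADC * ADCf / p$eps_ADC * (p$Ag_ex - ADCb)
  influx <- p$Kin_Drug * (p$V_cell / (TV_L * p$eps_Drug)) * DRGf

  dADCf <- flux_ADC / TV_L +
    (-bind + p$Koff_ADC * ADCb) * NC * SF / TV_L -
    p$Kdec_P * ADCf
  dDRGf <- flux_Drug + p$Kdec_P * ADCf * DAR * TV_L +
    (p$Kdec_P * ADCb * DAR + p$Kout_Drug * DFC) * NC * SF -
    influx * NC
  if (death_release) {
    rel <- TV4_mm3 * p$cells_per_mm3 * SF / p$tau
    dADCf <- dADCf + rel *
      (ADCb + cell_state[["ADClyso_cell"]]) / TV_L
    dDRGf <- dDRGf + rel * (DFC + cell_state[["Drugb_cell"]])
  }
  list(derivatives = c(ADCf_ex = dADCf, Drugf_ex = dDRGf),
       flux_ADC = flux_ADC, flux_Drug = flux_Drug)
}
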