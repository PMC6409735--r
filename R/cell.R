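# Single-cell disposition: antigen binding and internalization of the
# conjugate, lysosomal degradation releasing payload, payload exchange with
# the extracellular space, tubulin binding, and dilution of all species by
# cell growth.  Per-cell species are molecule counts.

#' Single-cell right-hand side
#'
#' Derivatives (molecules/cell/day) of bound conjugate, endosomal/lysosomal
#' conjugate, free cytoplasmic payload and tubulin-bound payload.  Binding
#' acts on the free interstitial conjugate concentration
#' (`ADCf_ex / eps_ADC`); degraded conjugate releases `DAR` payload
#' molecules each; every species is diluted at the tumor growth rate
#' `0.693/DT`.
#'
#' @param cell Named vector with `ADCb_cell`, `ADClyso_cell`, `Drugf_cell`,
#'   `Drugb_cell` (molecules/cell).
#' @param ADCf_ex Tumor extracellular conjugate, nM per total tumor volume.
#' @param Drugf_ex Tumor extracellular payload amount, nmol.
#' @param TV_mm3 Total tumor volume, mm^3.
#' @param p An [adc_params()] set.
#' @param DAR Current average drug-to-antibody ratio.
#' @return Named vector of derivatives, molecules/cell/day.
#' @export
cell_rhs <- function(cell, ADCf_ex, Drugf_ex, TV_mm3, p, DAR) {
  TV_L <- TV_mm3 * 1e-6
  Kg <- growth_rate(p$DT)
  tubm <- tubulin_molecules_per_cell(p$Tub_total, p$V_cell)
  ADCb <- cell[["ADCb_cell"]]; LYSO <- cell[["ADClyso_cell"]]
  DFC <- cell[["Drugf_cell"]]; DBC <- cell[["Drugb_cell"]]

  bind <- p$Kon_ADC * ADCf_ex / p$eps_ADC * (p$Ag_ex - ADCb)
  # mass action on the intracellular free payload concentration, nM
  tubb <- p$Kon_Tub * (SF / p$V_cell) * DFC * (tubm - DBC)
  influx <- p$Kin_Drug * (p$V_cell / (TV_L * p$eps_Drug)) * (Drugf_ex / SF)

  c(ADCb_cell = bind - p$Koff_ADC * ADCb -
      (p$Kdec_P + p$Kint_ADC) * ADCb - Kg * ADCb,
    ADClyso_cell = p$Kint_ADC * ADCb - p$Kdeg_ADC * LYSO - Kg * LYSO,
    Drugf_cell = p$Kdeg_ADC * LYSO * DAR - p$Kout_Drug * DFC -
      tubb + p$Koff_Tub * DBC + influx - Kg * DFC,
    Drugb_cell = tubb - p$Koff_Tub * DBC - Kg * DBC)
}

#' Percent tubulin occupancy
#'
#' Fraction of intracellular tubulin bound by payload, in percent; the
#' pharmacodynamic driver of cell killing.
#'
#' @param Drugb_cell Tubulin-bound payload, molecules/cell.
#' @param p An [adc_params()] set (supplies total tubulin per cell).
#' @return Occupancy in `[0, 100]`.
#' @export
tubulin_occupancy <- function(Drugb_cell, p) {
  tubm <- tubulin_molecules_per_cell(p$Tub_total, p$V_cell)
  100 * Drugb_cell / tubm
}

#' Equilibrium receptor occupancy (analytic binding oracle)
#'
#' Steady-state bound amount for simple reversible binding at constant free
#' ligand concentration: `Ag * C / (Koff/Kon + C)`.
#'
#' @param C_free Free ligand concentration, nM.
#' @param Ag Binding capacity (molecules/cell).
#' @param Kon Association rate, 1/nM/day.
#' @param Koff Dissociation rate, 1/day.
#' @return Bound molecules/cell at equilibrium.
#' @export
cell_equilibrium_bound <- function(C_free, Ag, Kon, Koff) {
  if (Kon <= 0 || Koff < 0) stop("rates must be positive")
  Ag * C_free / (Koff / Kon + C_free)
}
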