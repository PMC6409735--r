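# Plasma disposition of the conjugate and free payload: linear
# two-compartment models coupled through catabolism and non-specific
# deconjugation, with the average DAR declining first-order.

#' Plasma right-hand side
#'
#' Time derivatives of the five plasma states: conjugate amounts in central
#' and peripheral compartments (nmol), free payload concentrations (nM) and
#' average DAR.  Both the catabolic clearance and the deconjugation routes
#' of the conjugate form free payload, scaled by the current DAR.  Tumor
#' coupling fluxes are supplied by the tumor module (zero when simulating
#' plasma alone).
#'
#' @param state Named vector with `X1_ADC`, `X2_ADC` (nmol), `C1_Drug`,
#'   `C2_Drug` (nM), `DAR`.
#' @param p An [adc_params()] set.
#' @param tumor_flux_ADC Net conjugate flux into the tumor, nmol/day.
#' @param tumor_flux_Drug Net payload flux into the tumor, nmol/day.
#' @return Named vector of derivatives (nmol/day, nM/day, 1/day).
#' @export
plasma_rhs <- function(state, p, tumor_flux_ADC = 0, tumor_flux_Drug = 0) {
  bw <- p$body_weight
  V1A <- p$V1_ADC * bw; V2A <- p$V2_ADC * bw
  V1D <- p$V1_Drug * bw; V2D <- p$V2_Drug * bw
  CLA <- p$CL_ADC * bw; CLDA <- p$CLD_ADC * bw
  CLD <- p$CL_Drug * bw; CLDD <- p$CLD_Drug * bw
  X1 <- state[["X1_ADC"]]; X2 <- state[["X2_ADC"]]
  C1 <- state[["C1_Drug"]]; C2 <- state[["C2_Drug"]]
  DAR <- state[["DAR"]]
  c(X1_ADC = -(CLA + CLDA) / V1A * X1 + CLDA / V2A * X2 - p$Kdec_P * X1 -
      tumor_flux_ADC,
    X2_ADC = CLDA / V1A * X1 - CLDA / V2A * X2,
    C1_Drug = -(CLD + CLDD) / V1D * C1 + CLDD / V1D * C2 +
      p$Kdec_P * X1 * DAR / V1D + CLA * DAR * X1 / (V1A * V1D) -
      tumor_flux_Drug / V1D,
    C2_Drug = CLDD / V2D * (C1 - C2),
    DAR = -p$Kdec_P * DAR)
}

#' Closed-form two-compartment bolus solution
#'
#' Exact bi-exponential concentration after an IV bolus into a linear
#' two-compartment model with first-order loss `CL/V1 + extra_loss_rate`
#' from the central compartment.  Serves as an analytic oracle for the
#' integrated plasma model in tests.
#'
#' @param dose Bolus amount (same mass unit as desired concentration times
#'   `V1`, e.g. nmol for nM).
#' @param CL,CLD Central and distributional clearances (L/day).
#' @param V1,V2 Central and peripheral volumes (L).
#' @param extra_loss_rate Additional first-order loss from central (1/day),
#'   e.g. the deconjugation rate.
#' @param t Times (days).
#' @return Central-compartment concentrations at `t`.
#' @export
two_compartment_closed_form <- function(dose, CL, CLD, V1, V2,
                                        extra_loss_rate = 0, t) {
  k10 <- CL / V1 + extra_loss_rate
  k12 <- CLD / V1
  k21 <- CLD / V2
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  if (alpha == beta) return(dose / V1 * exp(-alpha * t))
  A <- (alpha - k21) / (alpha - beta)
  B <- (k21 - beta) / (alpha - beta)
  dose / V1 * (A * exp(-alpha * t) + B * exp(-beta * t))
}

#' Average DAR over time
#'
#' The average drug-to-antibody ratio declines first-order with the
#' non-specific deconjugation rate: `DAR0 * exp(-Kdec_P * t)`.
#'
#' @param DAR0 Initial average DAR.
#' @param Kdec_P Deconjugation rate, 1/day.
#' @param t Times (days).
#' @return DAR values.
#' @export
dar_profile <- function(DAR0, Kdec_P, t) {
  if (DAR0 < 0) stop("DAR0 must be non-negative")
  DAR0 * exp(-Kdec_P * t)
}
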