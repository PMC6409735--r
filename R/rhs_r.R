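# Readable R composition of the full right-hand side from the module-level
# pieces.  The compiled C version in src/ is the production integrator; this
# one documents the coupling and backs the consistency tests.

#' Full-system right-hand side in R
#'
#' Composes [plasma_rhs()], [tumor_ex_rhs()], [cell_rhs()] and [tgi_rhs()]
#' into the complete 15-state derivative, in a form usable directly by
#' `deSolve::ode`.  Intended for documentation and cross-checking against
#' the compiled model; simulations should use [simulate_adc()].
#'
#' @param t Time (days; unused, the system is autonomous between doses).
#' @param y Named state vector of the 15 system states.
#' @param parms A list with elements `p` (an [adc_params()] set) and logical
#'   flags `kill`, `release`, `tumor`.
#' @return A list with the derivative vector, as deSolve expects.
#' @export
adc_rhs_r <- function(t, y, parms) {
  p <- parms$p
  y <- pmax(y, 0)
  tvn <- c("TV1", "TV2", "TV3", "TV4")
  if (!isTRUE(parms$tumor)) {
    d <- stats::setNames(numeric(length(y)), names(y))
    d[names(plasma_rhs(y, p))] <- plasma_rhs(y, p)
    return(list(d))
  }
  TV_mm3 <- sum(y[tvn])
  cell <- y[c("ADCb_cell", "ADClyso_cell", "Drugf_cell", "Drugb_cell")]
  tum <- tumor_ex_rhs(y, y, cell, TV_mm3, TV4_mm3 = y[["TV4"]], p,
                      death_release = isTRUE(parms$release))
  dplasma <- plasma_rhs(y, p, tumor_flux_ADC = tum$flux_ADC,
                        tumor_flux_Drug = tum$flux_Drug)
  dcell <- cell_rhs(cell, y[["ADCf_ex"]], y[["Drugf_ex"]], TV_mm3, p,
                    DAR = y[["DAR"]])
  occ <- if (isTRUE(parms$kill)) tubulin_occupancy(y[["Drugb_cell"]], p) else 0
  dtv <- tgi_rhs(y[tvn], occ, p)
  list(c(dplasma, tum$derivatives, dcell, dtv)[names(y)])
}
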