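# Assembly and integration of the coupled 15-state system:
# plasma (X1_ADC, X2_ADC, C1_Drug, C2_Drug, DAR), tumor extracellular
# (ADCf_ex nM, Drugf_ex nmol), single cell (ADCb, ADClyso, Drugf, Drugb in
# molecules/cell), tumor volume compartments (TV1..TV4 mm^3).

.state_names <- c("X1_ADC", "X2_ADC", "C1_Drug", "C2_Drug", "DAR",
                  "ADCf_ex", "Drugf_ex",
                  "ADCb_cell", "ADClyso_cell", "Drugf_cell", "Drugb_cell",
                  "TV1", "TV2", "TV3", "TV4")

# parameter vector handed to the compiled right-hand side; clearances and
# volumes are converted per-animal here so that absolute tumor volume (L)
# and per-animal amounts (nmol) coexist consistently
.sim_parms <- function(p, kill_on, release_on, tumor_on) {
  bw <- p$body_weight
  c(CLA = p$CL_ADC * bw, CLDA = p$CLD_ADC * bw,
    V1A = p$V1_ADC * bw, V2A = p$V2_ADC * bw,
    CLD_ = p$CL_Drug * bw, CLDD = p$CLD_Drug * bw,
    V1D = p$V1_Drug * bw, V2D = p$V2_Drug * bw,
    KDEC = p$Kdec_P,
    KVA = 2 * p$P_ADC * p$R_cap / p$R_Krogh^2,
    SDA = 6 * p$D_ADC,
    KVD = 2 * p$P_Drug * p$R_cap / p$R_Krogh^2,
    SDD = 6 * p$D_Drug,
    EPSA = p$eps_ADC, EPSD = p$eps_Drug,
    KONA = p$Kon_ADC, KOFFA = p$Koff_ADC,
    KINT = p$Kint_ADC, KDEG = p$Kdeg_ADC,
    KONT = p$Kon_Tub, KOFFT = p$Koff_Tub,
    TUBM = tubulin_molecules_per_cell(p$Tub_total, p$V_cell),
    KIN = p$Kin_Drug, KOUT = p$Kout_Drug,
    AG = p$Ag_ex, VCELL = p$V_cell, SF = SF,
    CPM = p$cells_per_mm3,
    KG = growth_rate(p$DT),
    KMAX = p$Kmax, KC50 = p$KC50, GAM = p$gamma, TAU = p$tau,
    KILL_ON = as.numeric(kill_on), RELEASE_ON = as.numeric(release_on),
    TUMOR_ON = as.numeric(tumor_on))
}

#' Simulate the systems PK-PD model
#'
#' Integrates the full coupled system for a given parameter set and IV bolus
#' regimen.  Two staged modes mirror the model's development: `"pk"`
#' simulates plasma PK, tumor distribution and single-cell disposition with
#' the tumor growing unperturbed (used for PK fitting and exposure
#' summaries); `"pkpd"` additionally turns on tubulin-occupancy-driven
#' killing and the release of intracellular content from dying cells.
#'
#' @param params An [adc_params()] parameter set.
#' @param dose IV bolus dose in mg/kg (single number; repeated doses via
#'   `dose_times`).
#' @param times Output time grid in days (strictly increasing, starting at
#'   the first dose or earlier).
#' @param mode `"pk"` or `"pkpd"`.
#' @param tv0 Initial tumor volume in mm^3.  Defaults to 500 for `"pk"`
#'   (tumor PK studies started at ~500 mm^3) and 375 for `"pkpd"` (TGI
#'   studies started at ~350-400 mm^3).
#' @param dose_times Days at which the bolus is given (default a single dose
#'   at the start of the grid).
#' @param tumor If `FALSE` the tumor is decoupled entirely (plasma-only
#'   disposition; used for the plasma-stage fit).
#' @param init Optional named vector overriding initial states (advanced use
#'   and testing).
#' @param rtol,atol Integrator tolerances (lsoda).
#' @return An object of class `adc_sim` with the time grid, state matrix,
#'   parameters and dosing metadata.  Use [sim_observables()] to obtain
#'   analyte profiles.
#' @export
simulate_adc <- function(params, dose = 10,
                         times = seq(0, 7, by = 0.01),
                         mode = c("pk", "pkpd"), tv0 = NULL,
                         dose_times = times[1], tumor = TRUE,
                         init = NULL, rtol = 1e-8, atol = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "adc_params"))
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  if (any(dose < 0)) stop("dose must be non-negative")
  if (is.null(tv0)) tv0 <- if (mode == "pk") 500 else 375
  if (tv0 <= 0) stop("tv0 must be positive")

  y0 <- stats::setNames(numeric(15), .state_names)
  y0["DAR"] <- params$DAR0
  y0["TV1"] <- tv0
  amt <- dose_to_nmol(dose, params$MW_ADC, params$body_weight)$nmol
  events <- NULL
  if (times[1] %in% dose_times) y0["X1_ADC"] <- y0["X1_ADC"] + amt
  later <- setdiff(dose_times, times[1])
  if (length(later)) {
    events <- list(data = data.frame(var = "X1_ADC", time = later,
                                     value = amt, method = "add"))
  }
  if (!is.null(init)) {
    bad <- setdiff(names(init), .state_names)
    if (length(bad)) stop("unknown state(s): ", paste(bad, collapse = ", "))
    y0[names(init)] <- init
  }

  pv <- .sim_parms(params,
                   kill_on = mode == "pkpd",
                   release_on = mode == "pkpd",
                   tumor_on = tumor)
  if (is.null(atol)) {
    # absolute tolerances scaled by typical state magnitude
    atol <- stats::setNames(rep(1e-10, 15), .state_names)
    atol[c("TV1", "TV2", "TV3", "TV4")] <- 1e-6
    atol[c("ADCb_cell", "ADClyso_cell", "Drugf_cell", "Drugb_cell")] <- 1e-6
  }
  out <- deSolve::ode(y = y0, times = times, func = "adc_derivs",
                      parms = pv, dllname = "adcpkpd",
                      initfunc = "adc_initmod",
                      method = "lsoda", rtol = rtol, atol = atol,
                      events = events, maxsteps = 50000)
  if (attr(out, "istate")[1] < 0) {
    stop("integration failed at t = ", max(out[, 1]),
         " (dose ", dose, " mg/kg, mode ", mode, ")")
  }
  states <- out[, -1, drop = FALSE]
  # stiff solvers may transiently undershoot zero; clip within a small band,
  # error beyond it
  band <- -1e-6 * pmax(apply(abs(states), 2, max), 1)
  low <- sweep(states, 2, band, `<`)
  if (any(low)) {
    stop("negative state beyond tolerance band: ",
         paste(unique(colnames(states)[which(low, arr.ind = TRUE)[, 2]]),
               collapse = ", "))
  }
  states[states < 0] <- 0
  structure(list(times = out[, 1], states = states, params = params,
                 dose = dose, mode = mode, tv0 = tv0),
            class = "adc_sim")
}

#' @export
print.adc_sim <- function(x, ...) {
  cat("<adc_sim>", x$params$model, "model,", x$dose, "mg/kg, mode", x$mode,
      "\n  ", length(x$times), "time points over",
      diff(range(x$times)), "days\n")
  invisible(x)
}

#' Analyte observables from a state matrix
#'
#' Maps raw ODE states to the measurable analytes: plasma and tumor total
#' trastuzumab (nM), unconjugated MMAE (nM), total MMAE (conjugated plus
#' unconjugated, nM), average DAR, percent tubulin occupancy, and total
#' tumor volume (mm^3).  Tumor concentrations are per total tumor volume,
#' matching homogenate-based assays.
#'
#' @param sim An `adc_sim` object.
#' @param long If `TRUE` (default) return a long data frame with columns
#'   `time`, `matrix`, `analyte`, `value`; otherwise a wide data frame.
#' @return A data frame of observables.
#' @export
sim_observables <- function(sim, long = TRUE) {
  p <- sim$params
  s <- sim$states
  V1A <- p$V1_ADC * p$body_weight
  TVmm3 <- s[, "TV1"] + s[, "TV2"] + s[, "TV3"] + s[, "TV4"]
  TV_L <- TVmm3 * 1e-6
  NC <- TVmm3 * p$cells_per_mm3
  cell_to_nM <- NC * SF / TV_L  # molecules/cell -> nM per tumor volume
  tubm <- tubulin_molecules_per_cell(p$Tub_total, p$V_cell)

  plasma_trast <- s[, "X1_ADC"] / V1A
  plasma_unconj <- s[, "C1_Drug"]
  plasma_total <- s[, "DAR"] * plasma_trast + plasma_unconj
  tumor_trast <- s[, "ADCf_ex"] +
    (s[, "ADCb_cell"] + s[, "ADClyso_cell"]) * cell_to_nM
  tumor_unconj <- s[, "Drugf_ex"] / TV_L +
    (s[, "Drugf_cell"] + s[, "Drugb_cell"]) * cell_to_nM
  tumor_total <- tumor_unconj + s[, "DAR"] * tumor_trast
  occ <- 100 * s[, "Drugb_cell"] / tubm

  wide <- data.frame(time = sim$times,
                     plasma.total_trastuzumab = plasma_trast,
                     plasma.unconjugated_mmae = plasma_unconj,
                     plasma.total_mmae = plasma_total,
                     plasma.dar = s[, "DAR"],
                     tumor.total_trastuzumab = tumor_trast,
                     tumor.unconjugated_mmae = tumor_unconj,
                     tumor.total_mmae = tumor_total,
                     tumor.tubulin_occupancy = occ,
                     tumor.tumor_volume = TVmm3)
  if (!long) return(wide)
  cols <- setdiff(names(wide), "time")
  parts <- strsplit(cols, ".", fixed = TRUE)
  do.call(rbind, lapply(seq_along(cols), function(i) {
    data.frame(time = wide$time,
               matrix = parts[[i]][1],
               analyte = parts[[i]][2],
               value = wide[[cols[i]]])
  }))
}

#' Extract one observable curve from a simulation
#'
#' @param sim An `adc_sim` object.
#' @param matrix `"plasma"` or `"tumor"`.
#' @param analyte Analyte name as in [sim_observables()].
#' @return A data frame with `time` and `value`.
#' @export
sim_curve <- function(sim, matrix, analyte) {
  obs <- sim_observables(sim)
  out <- obs[obs$matrix == matrix & obs$analyte == analyte,
             c("time", "value")]
  if (!nrow(out)) stop("no such observable: ", matrix, "/", analyte)
  rownames(out) <- NULL
  out
}
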