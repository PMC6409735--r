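# Parameter housing: every model symbol with explicit units, converted once
# at load time to the internal unit system (days, litres, nmol, nM,
# molecules/cell, mm^3).  The bundled YAML file keeps the published units
# (cell-level rates per hour); the loader multiplies per-hour rates by 24 so
# that everything reaching the ODE right-hand side is per-day.

.per_hour_units <- c("1/h", "1/nM/h")

#' Load a systems PK-PD parameter set
#'
#' Reads a structured YAML parameter file (see
#' `system.file("extdata", "tvcmmae_params.yaml", package = "adcpkpd")` for
#' the bundled trastuzumab-vc-MMAE set), converts per-hour rates to per-day,
#' selects the tumor-model-specific antigen density and doubling time, and
#' validates the result.
#'
#' @param model Which xenograft model to parameterize: `"n87"` (HER2-high)
#'   or `"mcf7"` (HER2-low GFP-MCF7).
#' @param file Path to a parameter YAML file; default is the bundled set.
#' @param ... Named numeric overrides applied after loading (e.g.
#'   `Ag_ex = 5e4`, `Kdec_P = 0.2`).
#' @return An object of class `adc_params`: a named list of numeric values
#'   in internal units, with a `units` attribute and the model label.
#' @export
adc_params <- function(model = c("n87", "mcf7"), file = NULL, ...) {
  model <- match.arg(model)
  if (is.null(file)) {
    file <- system.file("extdata", "tvcmmae_params.yaml", package = "adcpkpd")
  }
  raw <- yaml::read_yaml(file)

  grab <- function(block) {
    out <- list()
    units <- character()
    for (nm in names(block)) {
      entry <- block[[nm]]
      if (!is.list(entry) || is.null(entry$value)) next
      val <- as.numeric(entry$value)
      unit <- if (is.null(entry$unit)) "" else entry$unit
      if (unit %in% .per_hour_units) {
        val <- val * 24
        unit <- sub("/h$", "/day", unit)
      }
      out[[nm]] <- val
      units[nm] <- unit
    }
    attr(out, "units") <- units
    out
  }

  p <- list()
  units <- character()
  for (blk in c("plasma", "tumor_distribution", "single_cell", "pd",
                "assumptions")) {
    b <- raw[[blk]]
    # per-model entries hold one sub-entry per tumor model
    for (nm in names(b)) {
      if (is.list(b[[nm]]) && is.null(b[[nm]]$value) &&
          all(c("n87", "mcf7") %in% names(b[[nm]]))) {
        b[[nm]] <- b[[nm]][[model]]
      }
    }
    g <- grab(b)
    units <- c(units, attr(g, "units"))
    p <- c(p, g)
  }
  names(units) <- names(p)
  p$body_weight <- p$body_weight %||% 0.02
  p$MW_ADC <- p$MW_ADC %||% 150000
  # inter-individual variability: Table percentages -> log-normal sd
  p$iiv_Kmax <- (p$iiv_Kmax %||% 0) / 100
  p$iiv_tau <- (p$iiv_tau %||% 0) / 100
  units["iiv_Kmax"] <- units["iiv_tau"] <- "sd of log"
  p$model <- model

  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    for (nm in names(dots)) p[[nm]] <- dots[[nm]]
  }

  structure(p, units = units, class = "adc_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a parameter set against its structural invariants
#'
#' Checks strict positivity of rates and volumes, void-volume fractions in
#' (0, 1], `R_Krogh > R_cap`, `KC50` in (0, 100], and the definitional
#' identity `SF * AVOGADRO * 1e-9 == 1`.
#'
#' @param p An `adc_params` object.
#' @return `p`, invisibly; errors describe the first violated invariant.
#' @export
validate_params <- function(p) {
  pos <- c("CL_ADC", "CLD_ADC", "V1_ADC", "V2_ADC", "CL_Drug", "CLD_Drug",
           "V1_Drug", "V2_Drug", "R_cap", "R_Krogh", "P_ADC", "P_Drug",
           "D_ADC", "D_Drug", "Kon_ADC", "Koff_ADC", "Kint_ADC", "Kdeg_ADC",
           "Kon_Tub", "Koff_Tub", "Tub_total", "Kin_Drug", "Kout_Drug",
           "Ag_ex", "V_cell", "cells_per_mm3", "Kmax", "gamma", "tau", "DT",
           "MW_ADC", "body_weight")
  for (nm in pos) {
    if (is.null(p[[nm]]) || !is.finite(p[[nm]]) || p[[nm]] <= 0) {
      stop("parameter ", nm, " must be a positive finite number")
    }
  }
  if (p$Kdec_P < 0) stop("Kdec_P must be non-negative")
  if (p$DAR0 < 0) stop("DAR0 must be non-negative")
  for (nm in c("eps_ADC", "eps_Drug")) {
    if (p[[nm]] <= 0 || p[[nm]] > 1) stop(nm, " must be in (0, 1]")
  }
  if (p$R_Krogh <= p$R_cap) stop("R_Krogh must exceed R_cap")
  if (p$KC50 <= 0 || p$KC50 > 100) stop("KC50 must be in (0, 100]")
  stopifnot(abs(SF * AVOGADRO * 1e-9 - 1) < 1e-12)
  invisible(p)
}

#' @export
print.adc_params <- function(x, ...) {
  cat("<adc_params> tumor model:", x$model, "\n")
  units <- attr(x, "units")
  nums <- names(x)[vapply(x, is.numeric, logical(1))]
  df <- data.frame(value = unlist(x[nums]),
                   unit = unname(units[nums]))
  print(df, ...)
  invisible(x)
}

#' Serialize a parameter set back to YAML
#'
#' Writes a flat YAML map of values with unit strings, readable again by
#' [read_params()].  Used to snapshot fitted parameter sets.
#'
#' @param p An `adc_params` object.
#' @param path Output file path.
#' @export
write_params <- function(p, path) {
  units <- attr(p, "units")
  nums <- names(p)[vapply(p, is.numeric, logical(1))]
  out <- lapply(nums, function(nm) {
    list(value = p[[nm]],
         unit = if (nm %in% names(units)) units[[nm]] else "")
  })
  names(out) <- nums
  yaml::write_yaml(list(model = p$model, parameters = out), path)
  invisible(path)
}

#' Read a flat parameter snapshot written by [write_params()]
#'
#' @param path File written by [write_params()].
#' @return An `adc_params` object.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  p <- adc_params(model = raw$model)
  for (nm in names(raw$parameters)) {
    p[[nm]] <- as.numeric(raw$parameters[[nm]]$value)
  }
  validate_params(p)
  p
}
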