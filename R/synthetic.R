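# Synthetic xenograft study generator.  Emulates the statistical structure
# of the tool-ADC studies: destructive plasma/tumor PK sampling at
# 10 min / 24 h / 72 h / 168 h with n = 3 per terminal time, and
# twice-weekly tumor-volume measurements at 1-10 mg/kg with n = 7 per arm;
# residual error follows the combined (additive + proportional) variance
# model Var = (sigma_int + sigma_slope * Y)^2, and subject-level log-normal
# variability can be applied to Kmax and tau.

#' Tumor PK study design
#'
#' @param model Tumor model, `"n87"` or `"mcf7"`.
#' @param dose IV bolus dose, mg/kg.
#' @param n_animals Animals per group (each gives an early plasma sample).
#' @param n_per_time Animals sacrificed per terminal time.
#' @param plasma_times Plasma sampling times, days (default 10 min, 1, 3, 7).
#' @param tumor_times Destructive tumor sampling times, days.
#' @param tv0 Tumor volume at dosing, mm^3.
#' @param sigma_int,sigma_slope Residual-error parameters shared by all
#'   concentration streams (additive part in nM, proportional part
#'   dimensionless).
#' @param seed Mandatory RNG seed for reproducibility.
#' @return A `study_design` list.
#' @export
pk_design <- function(model = c("n87", "mcf7"), dose = 10, n_animals = 9,
                      n_per_time = 3,
                      plasma_times = c(10 / 1440, 1, 3, 7),
                      tumor_times = c(1, 3, 7), tv0 = 500,
                      sigma_int = 0, sigma_slope = 0.1, seed) {
  if (missing(seed)) stop("a seed is required for reproducible generation")
  stopifnot(n_animals >= 1, n_per_time >= 1, dose >= 0, tv0 > 0,
            sigma_int >= 0, sigma_slope >= 0, sigma_int + sigma_slope > 0)
  structure(list(kind = "pk", model = match.arg(model), dose = dose,
                 n_animals = n_animals, n_per_time = n_per_time,
                 plasma_times = plasma_times, tumor_times = tumor_times,
                 tv0 = tv0, sigma_int = sigma_int, sigma_slope = sigma_slope,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Tumor growth inhibition study design
#'
#' Twice-weekly measurements are realized as the day pattern
#' `0, 3, 7, 10, 14, ...` out to `horizon` days; animals are censored once
#' their volume exceeds `cap` (the permissible limit).
#'
#' @param model Tumor model.
#' @param doses Dose arms in mg/kg (0 = vehicle control).
#' @param n_per_arm Animals per arm.
#' @param horizon Last measurement day.
#' @param tv0 Volume at randomization, mm^3.
#' @param sigma_int,sigma_slope Residual error on volumes (mm^3 and
#'   dimensionless).
#' @param iiv_Kmax,iiv_tau Log-normal subject-level standard deviations for
#'   the kill rate and transit time (0 disables).
#' @param cap Censoring volume, mm^3.
#' @param seed Mandatory RNG seed.
#' @return A `study_design` list.
#' @export
tgi_design <- function(model = c("n87", "mcf7"),
                       doses = if (match.arg(model) == "n87")
                         c(0, 1, 3, 10) else c(0, 3, 5, 10),
                       n_per_arm = 7, horizon = 48, tv0 = 375,
                       sigma_int = 0, sigma_slope = 0.1,
                       iiv_Kmax = 0, iiv_tau = 0, cap = 2000, seed) {
  if (missing(seed)) stop("a seed is required for reproducible generation")
  stopifnot(n_per_arm >= 1, all(doses >= 0), tv0 > 0, horizon > 0,
            sigma_int >= 0, sigma_slope >= 0, sigma_int + sigma_slope > 0)
  days <- sort(unique(c(outer(c(0, 3), seq(0, horizon, by = 7), `+`))))
  days <- days[days <= horizon]
  structure(list(kind = "tgi", model = match.arg(model), doses = doses,
                 n_per_arm = n_per_arm, days = days, horizon = horizon,
                 tv0 = tv0, sigma_int = sigma_int, sigma_slope = sigma_slope,
                 iiv_Kmax = iiv_Kmax, iiv_tau = iiv_tau, cap = cap,
                 seed = as.integer(seed)),
            class = "study_design")
}

# additive noise with SD = sigma_int + sigma_slope * Y, truncated at zero
.add_noise <- function(Y, sigma_int, sigma_slope) {
  pmax(0, Y + stats::rnorm(length(Y), 0, sigma_int + sigma_slope * Y))
}

# multiplicative log-normal subject-level factors with log-sd omega
.iiv_factors <- function(n, omega) {
  exp(stats::rnorm(n, 0, omega))
}

#' Generate a synthetic tumor PK dataset
#'
#' Simulates the model at the design's true parameters (PK mode: no
#' killing), samples the three analytes at the design schedule, and adds
#' combined-error noise.  Every animal contributes an early plasma sample;
#' terminal plasma and tumor samples are destructive, so each animal
#' contributes one terminal time.
#'
#' @param design A [pk_design()].
#' @param params True parameters, an [adc_params()] set matching
#'   `design$model`.
#' @return A long observation table: `time`, `matrix`, `analyte`, `model`,
#'   `dose`, `subject`, `value`.
#' @export
generate_pk_dataset <- function(design, params) {
  stopifnot(inherits(design, "study_design"), design$kind == "pk")
  set.seed(design$seed)
  times <- sort(unique(c(0, design$plasma_times, design$tumor_times)))
  sim <- simulate_adc(params, dose = design$dose, times = times,
                      mode = "pk", tv0 = design$tv0)
  obs <- sim_observables(sim)
  analytes <- c("total_trastuzumab", "unconjugated_mmae", "total_mmae")

  pred <- function(mtx, an, tm) {
    obs$value[obs$matrix == mtx & obs$analyte == an &
                abs(obs$time - tm) < 1e-9]
  }
  rows <- list()
  terminal <- rep(design$tumor_times, each = design$n_per_time)
  for (a in seq_len(design$n_animals)) {
    id <- sprintf("%s_pk_%02d", design$model, a)
    early <- design$plasma_times[1]
    tms <- c(early, if (a <= length(terminal)) terminal[a])
    for (tm in tms) {
      for (an in analytes) {
        rows[[length(rows) + 1]] <- data.frame(
          time = tm, matrix = "plasma", analyte = an,
          model = design$model, dose = design$dose, subject = id,
          value = .add_noise(pred("plasma", an, tm),
                             design$sigma_int, design$sigma_slope))
      }
      if (tm %in% design$tumor_times) {
        for (an in analytes) {
          rows[[length(rows) + 1]] <- data.frame(
            time = tm, matrix = "tumor", analyte = an,
            model = design$model, dose = design$dose, subject = id,
            value = .add_noise(pred("tumor", an, tm),
                               design$sigma_int, design$sigma_slope))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic tumor growth inhibition dataset
#'
#' Per-subject kill rate and transit time are drawn log-normally when the
#' design's inter-individual variabilities are non-zero; control arms
#' involve no killing, so their trajectories ignore the PD variability.
#' Measurements stop (administrative censoring) once a subject's noisy
#' volume exceeds the design cap.
#'
#' @param design A [tgi_design()].
#' @param params True parameters matching `design$model`.
#' @return A long observation table with analyte `tumor_volume` (mm^3).
#' @export
generate_tgi_dataset <- function(design, params) {
  stopifnot(inherits(design, "study_design"), design$kind == "tgi")
  set.seed(design$seed)
  rows <- list()
  for (d in design$doses) {
    typical <- NULL
    for (s in seq_len(design$n_per_arm)) {
      id <- sprintf("%s_tgi_%g_%02d", design$model, d, s)
      use_iiv <- d > 0 && (design$iiv_Kmax > 0 || design$iiv_tau > 0)
      if (use_iiv) {
        ps <- params
        ps$Kmax <- params$Kmax * .iiv_factors(1, design$iiv_Kmax)
        ps$tau <- params$tau * .iiv_factors(1, design$iiv_tau)
        tv <- .tgi_curve(ps, d, design$days, design$tv0)
      } else {
        if (is.null(typical)) {
          typical <- .tgi_curve(params, d, design$days, design$tv0)
        }
        tv <- typical
      }
      y <- .add_noise(tv, design$sigma_int, design$sigma_slope)
      over <- which(y > design$cap)
      keep <- if (length(over)) seq_len(over[1]) else seq_along(y)
      rows[[length(rows) + 1]] <- data.frame(
        time = design$days[keep], matrix = "tumor",
        analyte = "tumor_volume", model = design$model, dose = d,
        subject = id, value = y[keep])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# typical (no-IIV) tumor-volume curve for one arm
.tgi_curve <- function(params, dose, days, tv0) {
  if (dose == 0) {
    return(tv0 * exp(growth_rate(params$DT) * days))
  }
  times <- sort(unique(c(0, days)))
  sim <- simulate_adc(params, dose = dose, times = times, mode = "pkpd",
                      tv0 = tv0, rtol = 1e-8)
  tv <- rowSums(sim$states[, c("TV1", "TV2", "TV3", "TV4")])
  tv[match(days, times)]
}
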