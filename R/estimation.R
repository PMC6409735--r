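# Staged maximum-likelihood calibration mirroring the model's sequential
# development: (1) plasma disposition of conjugate and payload plus the
# deconjugation rate; (2) per-model antigen density against tumor PK with
# plasma frozen; (3) kill parameters {Kmax, KC50, tau} against TGI curves
# with all PK frozen.  The residual model is the combined-error variance
# Var(t) = (sigma_int + sigma_slope * Y(t))^2; with a purely proportional
# error the per-stream sigma has a closed-form ML profile, which is used by
# default so no variance parameters need numerical search.

.stage_free <- list(plasma = c("CL_ADC", "CLD_ADC", "V1_ADC", "V2_ADC",
                               "Kdec_P"),
                    tumor = "Ag_ex",
                    pd = c("Kmax", "KC50", "tau"))

# normalize `params` to a named list of per-model parameter sets covering
# every model label in the data
.params_by_model <- function(params, data) {
  models <- unique(data$model)
  if (inherits(params, "adc_params")) {
    pl <- stats::setNames(lapply(models, function(m) {
      if (params$model == m) return(params)
      adc_params(m)
    }), models)
    if (length(models) == 1L) pl[[1]] <- params
    return(pl)
  }
  missing <- setdiff(models, names(params))
  if (length(missing)) {
    stop("no parameter set supplied for model(s): ",
         paste(missing, collapse = ", "))
  }
  params[models]
}

.apply_free <- function(params_list, free) {
  lapply(params_list, function(p) {
    for (nm in names(free)) p[[nm]] <- free[[nm]]
    p
  })
}

# model predictions aligned to the rows of a long observation table
.predict_stage <- function(stage, params_list, data, tv0 = NULL,
                           rtol = 1e-7) {
  Y <- rep(NA_real_, nrow(data))
  key <- function(d) paste(d$time, d$matrix, d$analyte)
  if (stage == "plasma") {
    # tumor-bearing study: simulate the full system per tumor model (tumor
    # and cell blocks frozen at their supplied values) so the plasma drain
    # into the tumor is part of the prediction
    for (m in unique(data$model)) {
      idx <- data$model == m
      dose <- unique(data$dose[idx])
      if (length(dose) != 1L) stop("plasma stage expects one dose per model")
      times <- sort(unique(c(0, data$time[idx])))
      sim <- simulate_adc(params_list[[m]], dose = dose, times = times,
                          mode = "pk", tv0 = tv0 %||% 500, rtol = rtol)
      obs <- sim_observables(sim)
      Y[idx] <- obs$value[match(key(data[idx, ]), key(obs))]
    }
  } else if (stage == "tumor") {
    stopifnot(length(params_list) == 1L)
    times <- sort(unique(c(0, data$time)))
    sim <- simulate_adc(params_list[[1]], dose = unique(data$dose),
                        times = times, mode = "pk", tv0 = tv0 %||% 500,
                        rtol = rtol)
    obs <- sim_observables(sim)
    Y <- obs$value[match(key(data), key(obs))]
  } else if (stage == "pd") {
    for (m in unique(data$model)) {
      p <- params_list[[m]]
      for (d in unique(data$dose[data$model == m])) {
        idx <- data$model == m & data$dose == d
        tms <- sort(unique(data$time[idx]))
        if (d == 0) {
          tv <- (tv0 %||% 375) * exp(growth_rate(p$DT) * tms)
        } else {
          sim <- simulate_adc(p, dose = d,
                              times = sort(unique(c(0, tms))),
                              mode = "pkpd", tv0 = tv0 %||% 375,
                              rtol = rtol)
          tvall <- rowSums(sim$states[, c("TV1", "TV2", "TV3", "TV4")])
          tv <- tvall[match(tms, sim$times)]
        }
        Y[idx] <- tv[match(data$time[idx], tms)]
      }
    }
  } else stop("unknown stage: ", stage)
  if (anyNA(Y)) stop("could not align predictions with observations")
  Y
}

#' Maximum-likelihood objective (-2 log-likelihood)
#'
#' Negative twice log-likelihood of a long observation table under the
#' combined-error variance model, evaluated at candidate values of the free
#' parameters.  With `var = "profile"` (default) a purely proportional
#' residual sigma is profiled out analytically per data stream
#' (matrix/analyte combination); alternatively supply fixed
#' `list(sigma_int =, sigma_slope =)` values.
#'
#' A simulation failure at the candidate parameters returns a large penalty
#' (1e10) with a warning rather than an error, so derivative-free optimizers
#' can route around pathological regions.
#'
#' @param free Named numeric vector of candidate parameter values (natural
#'   scale).
#' @param data Long observation table (`time`, `matrix`, `analyte`, `model`,
#'   `dose`, `value`).
#' @param config A list with `stage` (`"plasma"`, `"tumor"` or `"pd"`),
#'   `params` (per-model parameter list as produced internally by
#'   [fit_stage()]), and optional `tv0`, `rtol`.
#' @param var `"profile"` or a list with `sigma_int` and `sigma_slope`.
#' @return The scalar -2 log-likelihood (dropping constant terms for the
#'   profiled case).
#' @export
ml_objective <- function(free, data, config, var = "profile") {
  pl <- .apply_free(config$params, as.list(free))
  Y <- tryCatch(
    .predict_stage(config$stage, pl, data, tv0 = config$tv0,
                   rtol = config$rtol %||% 1e-7),
    error = function(e) {
      warning("simulation failed at candidate parameters: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
  if (is.null(Y)) return(1e10)
  y <- data$value
  if (identical(var, "profile")) {
    if (any(Y <= 0)) return(1e10)
    stream <- paste(data$matrix, data$analyte)
    obj <- 0
    for (s in unique(stream)) {
      i <- stream == s
      ss <- mean(((y[i] - Y[i]) / Y[i])^2)
      obj <- obj + sum(i) * (1 + log(ss)) + 2 * sum(log(Y[i]))
    }
    obj
  } else {
    V <- (var$sigma_int + var$sigma_slope * Y)^2
    if (any(V <= 0)) return(1e10)
    sum((y - Y)^2 / V + log(V))
  }
}

#' Fit one calibration stage by maximum likelihood
#'
#' Optimizes the stage's free parameters on the log scale (guaranteeing
#' positivity) with Nelder-Mead (Brent for a single parameter), optionally
#' from multiple jittered starts.  Precision (CV%) is obtained from the
#' inverse of the finite-difference Hessian of the objective at the optimum.
#'
#' Stage conventions: `"plasma"` frees
#' `{CL_ADC, CLD_ADC, V1_ADC, V2_ADC, Kdec_P}` against plasma analytes with
#' the tumor decoupled; `"tumor"` frees the per-cell antigen count `Ag_ex`
#' for a single tumor model with plasma frozen; `"pd"` frees
#' `{Kmax, KC50, tau}` (Hill coefficient and doubling times fixed) against
#' tumor-volume curves from all arms of both models.
#'
#' @param stage `"plasma"`, `"tumor"` or `"pd"`.
#' @param data Long observation table for the stage.
#' @param params Starting/frozen parameters: an [adc_params()] set or a
#'   named per-model list (required for `"pd"` with both models).
#' @param free Names of parameters to estimate (defaults per stage).
#' @param init Named numeric initial values (defaults to the values in
#'   `params`).
#' @param var Variance model passed to [ml_objective()].
#' @param n_start Number of optimizer starts (first at `init`, the rest
#'   log-normally jittered); default 5 for `"plasma"`, 1 otherwise.
#' @param jitter_sd Log-scale standard deviation of start jitter.
#' @param seed Seed for the start jitter.
#' @param compute_cv Compute CV% from the inverse Hessian?
#' @param tv0 Initial tumor volume (defaults: 500 PK stages, 375 PD).
#' @param rtol Integrator tolerance used during fitting.
#' @param control Passed to [stats::optim()] (Nelder-Mead).
#' @return An `adc_fit` object: estimates, CV%, objective value, per-stream
#'   profiled sigmas, convergence flag and stage label.
#' @export
fit_stage <- function(stage = c("plasma", "tumor", "pd"), data, params,
                      free = NULL, init = NULL, var = "profile",
                      n_start = if (stage == "plasma") 5 else 1,
                      jitter_sd = 0.2, seed = 1, compute_cv = TRUE,
                      tv0 = NULL, rtol = 1e-7, control = list()) {
  stage <- match.arg(stage)
  need <- c("time", "matrix", "analyte", "model", "dose", "value")
  if (!all(need %in% names(data))) {
    stop("observation table must have columns: ", paste(need, collapse = ", "))
  }
  if (stage %in% c("plasma", "tumor")) {
    data <- data[data$matrix == if (stage == "plasma") "plasma" else "tumor", ]
  }
  if (stage == "tumor" && length(unique(data$model)) != 1L) {
    stop("the tumor stage estimates Ag_ex for one tumor model at a time")
  }
  if (!nrow(data)) stop("no observations for stage ", stage)
  pl <- .params_by_model(params, data)
  free <- free %||% .stage_free[[stage]]
  init <- init %||% stats::setNames(
    vapply(free, function(nm) pl[[1]][[nm]], numeric(1)), free)
  config <- list(stage = stage, params = pl, tv0 = tv0, rtol = rtol)

  objfun <- function(logpar) {
    ml_objective(stats::setNames(exp(logpar), free), data, config, var)
  }
  l0 <- log(unlist(init[free]))
  set.seed(seed)
  starts <- lapply(seq_len(n_start), function(i) {
    if (i == 1) l0 else l0 + stats::rnorm(length(l0), 0, jitter_sd)
  })
  best <- NULL
  for (st in starts) {
    fit <- if (length(free) == 1L) {
      stats::optim(st, objfun, method = "Brent",
                   lower = st - log(100), upper = st + log(100))
    } else {
      ctrl <- utils::modifyList(list(maxit = 1000, reltol = 1e-8), control)
      stats::optim(st, objfun, method = "Nelder-Mead", control = ctrl)
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  est <- stats::setNames(exp(best$par), free)

  cv <- rep(NA_real_, length(free))
  singular <- FALSE
  if (compute_cv) {
    H <- tryCatch(pracma::hessian(objfun, best$par), error = function(e) NULL)
    cov <- if (!is.null(H)) tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(cov) && all(diag(cov) > 0)) {
      se_log <- sqrt(diag(cov))
      cv <- 100 * sqrt(exp(se_log^2) - 1)
    } else singular <- TRUE
  }

  # profiled per-stream residual sigmas at the optimum
  sigma <- NULL
  if (identical(var, "profile")) {
    Y <- .predict_stage(stage, .apply_free(pl, as.list(est)), data,
                        tv0 = tv0, rtol = rtol)
    stream <- paste(data$matrix, data$analyte)
    sigma <- vapply(split(seq_len(nrow(data)), stream), function(i) {
      sqrt(mean(((data$value[i] - Y[i]) / Y[i])^2))
    }, numeric(1))
  }

  structure(list(stage = stage, estimates = est,
                 cv_pct = stats::setNames(cv, free),
                 objective = best$value,
                 convergence = best$convergence == 0 && !singular,
                 hessian_singular = singular,
                 sigma_slope = sigma, n_obs = nrow(data)),
            class = "adc_fit")
}

#' @export
print.adc_fit <- function(x, ...) {
  cat("<adc_fit> stage:", x$stage, " (-2LL =", format(x$objective), ")\n")
  df <- data.frame(estimate = x$estimates, cv_pct = x$cv_pct)
  print(df, ...)
  if (!x$convergence) cat("  ** optimizer did not converge cleanly **\n")
  invisible(x)
}

#' Fit exponential growth to control-arm tumor volumes
#'
#' Nonlinear least-squares fit of `TV0 * exp(0.693/DT * t)` to pooled
#' control-arm measurements, returning the recovered doubling time.
#'
#' @param data Observation table restricted internally to `dose == 0` and
#'   analyte `tumor_volume`.
#' @param tv0 Starting value for the initial volume, mm^3.
#' @return List with `DT` (days), `TV0` (mm^3) and the `nls` fit object.
#' @export
fit_growth <- function(data, tv0 = 375) {
  d <- data[data$dose == 0 & data$analyte == "tumor_volume", ]
  if (!nrow(d)) stop("no control-arm tumor volumes in data")
  fit <- minpack.lm::nlsLM(value ~ v0 * exp(0.693 / DT * time),
                           data = d,
                           start = list(v0 = tv0, DT = 12),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  list(DT = unname(cf["DT"]), TV0 = unname(cf["v0"]), fit = fit)
}

#' Run the full sequential calibration
#'
#' Executes the three stages in order on a data bundle, freezing each
#' stage's estimates before the next: plasma disposition, then per-model
#' antigen density, then (after recovering doubling times from the control
#' arms) the kill parameters.  Stages whose data are absent are skipped with
#' a message; the PD stage refuses to run before the tumor stage.
#'
#' @param bundle List with elements `plasma`, `tumor` and `tgi`, each a long
#'   observation table (tumor may contain both models; they are fitted
#'   separately).
#' @param params Starting parameters: an [adc_params()] set or per-model
#'   named list.
#' @param ... Passed on to [fit_stage()].
#' @return List with the per-stage `adc_fit` objects (`plasma`, `tumor` per
#'   model, `growth` per model, `pd`) and `params`, the final per-model
#'   calibrated parameter sets.
#' @export
sequential_calibration <- function(bundle, params = adc_params("n87"), ...) {
  results <- list()
  all_models <- unique(unlist(lapply(bundle, function(b) b$model)))
  pl <- stats::setNames(lapply(all_models, function(m) {
    if (inherits(params, "adc_params")) {
      if (params$model == m) params else adc_params(m)
    } else params[[m]]
  }), all_models)

  if (!is.null(bundle$plasma)) {
    results$plasma <- fit_stage("plasma", bundle$plasma, pl[[1]], ...)
    pl <- .apply_free(pl, as.list(results$plasma$estimates))
  } else message("no plasma table: plasma stage skipped")

  if (!is.null(bundle$tumor)) {
    results$tumor <- list()
    for (m in unique(bundle$tumor$model)) {
      f <- fit_stage("tumor", bundle$tumor[bundle$tumor$model == m, ],
                     pl[[m]], ...)
      results$tumor[[m]] <- f
      pl[[m]]$Ag_ex <- unname(f$estimates["Ag_ex"])
    }
  } else message("no tumor table: tumor stage skipped")

  if (!is.null(bundle$tgi)) {
    if (is.null(bundle$tumor)) {
      stop("the PD stage requires the tumor stage to have run first")
    }
    results$growth <- list()
    for (m in unique(bundle$tgi$model)) {
      g <- fit_growth(bundle$tgi[bundle$tgi$model == m, ])
      results$growth[[m]] <- g
      pl[[m]]$DT <- g$DT
    }
    results$pd <- fit_stage("pd", bundle$tgi, pl, ...)
    pl <- .apply_free(pl, as.list(results$pd$estimates))
  } else message("no TGI table: PD stage skipped")

  results$params <- pl
  results
}
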