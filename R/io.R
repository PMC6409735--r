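# Tabular interchange and run configuration.  A single long CSV schema
# (time, matrix, analyte, model, dose, subject, value) serves simulation
# output, NCA input, fitting input and generated fixtures.

.obs_columns <- c("time", "matrix", "analyte", "model", "dose", "subject",
                  "value")

#' Write a long observation table to CSV
#'
#' @param data Observation table (see [generate_pk_dataset()]).
#' @param path Output CSV path.
#' @export
write_observations <- function(data, path) {
  missing <- setdiff(.obs_columns, names(data))
  if (length(missing)) {
    stop("observation table lacks column(s): ", paste(missing, collapse = ", "))
  }
  utils::write.csv(data[.obs_columns], path, row.names = FALSE)
  invisible(path)
}

#' Read a long observation table from CSV, validating the schema
#'
#' @param path CSV path written by [write_observations()] (or any file with
#'   the same columns).
#' @return A validated observation data frame.
#' @export
read_observations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.obs_columns, names(d))
  if (length(missing)) {
    stop("observation file lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(d$value < 0)) stop("negative observation values")
  if (any(!is.finite(d$time)) || any(d$time < 0)) stop("invalid times")
  d
}

.config_keys <- c("command", "model", "dose", "doses", "mode", "seed",
                  "out", "data", "params_file", "overrides", "tv0",
                  "t_end", "grid_step", "window", "stage", "n_per_arm",
                  "sigma_int", "sigma_slope", "iiv_Kmax", "iiv_tau",
                  "verbosity")

#' Parse and validate a run configuration file
#'
#' Reads a YAML (or JSON) configuration describing a run of one of the
#' top-level commands (`simulate`, `nca`, `fit`, `generate`, `recover`),
#' rejecting unknown keys by name so typos fail loudly, and filling
#' defaults.
#'
#' @param path YAML/JSON configuration file.
#' @return A named list of validated settings (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  defaults <- list(command = "simulate", model = "n87", dose = 10,
                   mode = "pk", seed = 1, t_end = 7,
                   grid_step = 0.01, verbosity = 1)
  cfg <- utils::modifyList(defaults, cfg)
  if (!cfg$command %in% c("simulate", "nca", "fit", "generate", "recover")) {
    stop("unknown command: ", cfg$command)
  }
  structure(cfg, class = "run_config")
}

#' Write a run configuration (round-trips through [read_run_config()])
#'
#' @param cfg A `run_config` or plain named list of known keys.
#' @param path Output YAML path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Reproducibility manifest for a run
#'
#' Captures everything needed to regenerate an output byte-identically:
#' package version, seed, parameter values and the run configuration.
#'
#' @param cfg A `run_config`.
#' @param params The parameter set used.
#' @return A list suitable for `jsonlite::write_json()`.
#' @export
run_manifest <- function(cfg, params) {
  list(package = "adcpkpd",
       version = as.character(utils::packageVersion("adcpkpd")),
       r_version = R.version.string,
       seed = cfg$seed,
       config = unclass(cfg),
       parameters = params[vapply(params, is.numeric, logical(1))])
}
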