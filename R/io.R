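# Structured-text interfaces: parameter files and tidy trajectory export.

#' Write model parameters to a YAML file
#'
#' @param params a `raasimParams` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeParameters <- function(params, path) {
  stopifnot(inherits(params, "raasimParams"))
  yaml::write_yaml(lapply(unclass(params), function(g) {
    if (inherits(g, "rateConstants")) unclass(g) else g
  }), path, precision = 12L)
  invisible(path)
}

#' Read model parameters from a YAML file
#'
#' @param path file written by [writeParameters()].
#' @return a `raasimParams` object.
#' @export
readParameters <- function(path) {
  raw <- yaml::read_yaml(path)
  p <- defaultParameters()
  for (grp in names(raw)) {
    if (grp == "rates") {
      p$rates <- do.call(rateConstants, raw$rates)
    } else {
      p[[grp]][names(raw[[grp]])] <- raw[[grp]]
    }
  }
  p
}

#' Per-patient record as a plain list (JSON-ready)
#'
#' Collects the demographics, genotype assignment, fitted parameter values,
#' baseline equilibrium, fit diagnostics and seed of a virtual patient into
#' nested plain lists, suitable for `jsonlite::write_json()` or YAML export.
#'
#' @param patient a `virtualPatient`.
#' @return a named list.
#' @export
patientRecord <- function(patient) {
  stopifnot(inherits(patient, "virtualPatient"))
  list(
    demographics = as.list(patient$demographics),
    group = patient$group, genotype = patient$genotype,
    cACE = patient$cACE, seed = patient$seed,
    parameters = lapply(unclass(patient$params), function(g) {
      if (inherits(g, "rateConstants")) unclass(g) else g
    }),
    baseline = unclass(patient$baseline)[],
    objective = patient$objective, penalty = patient$penalty,
    diagnostics = patient$diagnostics
  )
}

#' Tidy (long) form of a co-simulation trajectory
#'
#' @param run a `cosimResult` (or an `equilibriumSummary` carrying one).
#' @return data frame with columns `time` (model minutes), `variable`,
#'   `value`, suitable for CSV export or plotting.
#' @export
trajectoryTidy <- function(run) {
  if (inherits(run, "equilibriumSummary")) run <- attr(run, "run")
  if (!inherits(run, "cosimResult")) {
    stopTyped("invalidArgument", "run must be a cosimResult")
  }
  tr <- run$trajectory
  vars <- setdiff(colnames(tr), "time")
  data.frame(
    time = rep(tr[, "time"], times = length(vars)),
    variable = rep(vars, each = nrow(tr)),
    value = as.vector(tr[, vars]),
    stringsAsFactors = FALSE
  )
}
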