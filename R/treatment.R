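#' Construct a virtual patient object
#'
#' @param params fitted model parameters.
#' @param baseline baseline `equilibriumSummary`.
#' @param demographics named list/vector (SBP, DBP, HR, SV, BW, BMI, BH, sex)
#'   or `NULL`.
#' @param group ACE-activity group label (`"L"`, `"H"` or `NA`).
#' @param genotype `"II"`, `"ID"`, `"DD"` or `NA`.
#' @param objective,penalty fit diagnostics (NA when not fitted).
#' @param seed the per-patient seed (NA when not applicable).
#' @param diagnostics free-form list (optimizer traces, sodium-test result).
#' @return a `virtualPatient` object.
#' @export
virtualPatient <- function(params, baseline, demographics = NULL,
                           group = NA_character_, genotype = NA_character_,
                           objective = NA_real_, penalty = NA_real_,
                           seed = NA_integer_, diagnostics = list()) {
  structure(list(params = params, baseline = baseline,
                 demographics = demographics, group = group,
                 genotype = genotype, cACE = params$rates$cACE,
                 objective = objective, penalty = penalty, seed = seed,
                 diagnostics = diagnostics),
            class = "virtualPatient")
}

#' The default (calibration) patient
#'
#' The shipped model parameterisation at a chosen ACE activity, with its
#' baseline equilibrium solved. Used for the ACE-activity sweep, the drug
#' direction suite and the treatment-response contrasts.
#'
#' @param cACE ACE activity (1/h).
#' @return a `virtualPatient`.
#' @export
defaultPatient <- function(cACE = 54.1) {
  params <- defaultParameters(cACE = cACE)
  virtualPatient(params, steadyState(params))
}

#' @export
print.virtualPatient <- function(x, ...) {
  cat("Virtual patient")
  if (!is.na(x$group)) cat(sprintf(" [%s%s, cACE %.1f 1/h]", x$group,
                                   x$genotype, x$cACE))
  else cat(sprintf(" [cACE %.1f 1/h]", x$cACE))
  cat("\n")
  if (!is.null(x$demographics)) {
    d <- x$demographics
    cat(sprintf("  targets: SBP %.0f DBP %.0f HR %.0f SV %.0f; BW %.0f kg, BH %.0f cm, %s\n",
                d[["SBP"]], d[["DBP"]], d[["HR"]], d[["SV"]], d[["BW"]],
                d[["BH"]], d[["sex"]]))
  }
  cat(sprintf("  baseline: %.1f/%.1f mmHg, HR %.1f, SV %.1f mL\n",
              x$baseline$SBP, x$baseline$DBP, x$baseline$HR, x$baseline$SV))
  if (!is.na(x$objective)) {
    cat(sprintf("  fit objective %.3g, penalty %.3g\n", x$objective, x$penalty))
  }
  invisible(x)
}

#' Simulate an antihypertensive treatment course
#'
#' Treatment is modelled as an acute switch of the pharmacodynamic
#' multipliers at time zero: the patient leaves its baseline equilibrium and
#' the coupled model is run forward to the week-`duration` state (the model
#' typically settles into its new equilibrium within 1-2 model weeks, after
#' which the state no longer changes, so the endpoint equals that
#' equilibrium). Deterministic.
#'
#' @param patient a `virtualPatient` (or a `raasimParams`, in which case the
#'   baseline is solved first).
#' @param regimen a [buildRegimen()] result or character vector of
#'   `"name dose"` strings; the empty vector is placebo.
#' @param duration treatment duration in weeks.
#' @param catalogue drug catalogue.
#' @param ... passed to [simulateToEquilibrium()] (exchange interval etc.).
#' @return a `treatmentOutcome`: list with `baseline`, `endpoint`
#'   (equilibrium summaries) and `delta` (endpoint minus baseline, named
#'   vector over the shared numeric variables), plus the regimen.
#' @export
simulateTreatment <- function(patient, regimen = character(), duration = 4,
                              catalogue = drugCatalogue(), ...) {
  if (inherits(patient, "raasimParams")) {
    patient <- virtualPatient(patient, steadyState(patient))
  }
  if (!inherits(patient, "virtualPatient")) {
    stopTyped("invalidArgument", "patient must be a virtualPatient")
  }
  effects <- if (inherits(regimen, "effectMultipliers")) regimen
             else applyRegimen(regimen, catalogue)
  baseline <- patient$baseline
  endpoint <- tryCatch(
    simulateToEquilibrium(patient$params, effects, init = baseline,
                          horizon = duration * 7,
                          require_equilibrium = FALSE, ...),
    convergenceError = function(e) {
      stopTyped("convergenceError",
                paste("treatment simulation failed:", conditionMessage(e)))
    })
  vars <- intersect(names(baseline), names(endpoint))
  num <- vars[vapply(vars, function(v) is.numeric(baseline[[v]]), TRUE)]
  delta <- vapply(num, function(v) endpoint[[v]] - baseline[[v]], 0)
  structure(list(baseline = baseline, endpoint = endpoint, delta = delta,
                 regimen = regimen, duration = duration),
            class = "treatmentOutcome")
}

#' @export
print.treatmentOutcome <- function(x, ...) {
  reg <- if (is.character(x$regimen) && length(x$regimen)) {
    paste(x$regimen, collapse = " + ")
  } else if (inherits(x$regimen, "regimen") && any(x$regimen == 1)) {
    paste(names(x$regimen)[x$regimen == 1], collapse = " + ")
  } else "placebo"
  cat(sprintf("Treatment outcome after %g weeks: %s\n", x$duration, reg))
  cat(sprintf("  SBP %.1f -> %.1f (%+.1f), DBP %.1f -> %.1f (%+.1f) mmHg\n",
              x$baseline$SBP, x$endpoint$SBP, x$delta[["SBP"]],
              x$baseline$DBP, x$endpoint$DBP, x$delta[["DBP"]]))
  cat(sprintf("  PRA %+.1f%%, AngI %+.1f%%, AngII %+.1f%%, ALD %+.1f%%\n",
              100 * x$delta[["PRA"]] / x$baseline$PRA,
              100 * x$delta[["AngI"]] / x$baseline$AngI,
              100 * x$delta[["AngII"]] / x$baseline$AngII,
              100 * x$delta[["ALD"]] / x$baseline$ALD))
  invisible(x)
}
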