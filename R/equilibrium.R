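#' Equilibrium test on a sampled trajectory
#'
#' A model run is considered at equilibrium when every variable either stays
#' constant or oscillates steadily with a period equal to the cardiac cycle.
#' Both cases reduce to the same check on a uniformly sampled trajectory:
#' shifting the series by one period must reproduce it within tolerance
#' (a constant series is periodic for any period).
#'
#' @param series numeric vector or matrix (one column per variable) sampled
#'   at a uniform interval `dt`.
#' @param cycle_length the comparison period, in the same unit as `dt`.
#' @param tol relative window-to-window tolerance (deviations scaled by
#'   `max(|x|, 1)` per variable).
#' @param dt sampling interval of `series`.
#' @return `TRUE` if all variables are constant or cycle-periodic within
#'   `tol`, else `FALSE`.
#' @export
detectEquilibrium <- function(series, cycle_length, tol = 1e-3, dt = 1) {
  if (is.vector(series)) series <- matrix(series, ncol = 1)
  assertPositive(c(cycle_length, dt), "cycle_length and dt")
  shift <- max(1L, as.integer(round(cycle_length / dt)))
  n <- nrow(series)
  if (n < 2L * shift) {
    stopTyped("invalidArgument",
              "series must cover at least two comparison windows")
  }
  idx <- seq_len(n - shift)
  for (j in seq_len(ncol(series))) {
    x <- series[, j]
    scale <- max(abs(x), 1)
    if (max(abs(x[idx + shift] - x[idx])) / scale >= tol) return(FALSE)
  }
  TRUE
}

summaryFromCosim <- function(run, params, effects) {
  y <- run$state$renal
  fast <- run$trajectory[nrow(run$trajectory), ]
  MAP <- fast[["MAP"]]
  at1 <- at1Signal(y[["AngII"]], params, effects)
  sig <- at1Sigma(at1, params)
  cmd <- vascularCommands(sig, MAP, params, effects)
  haem <- renalHaemodynamics(sig, MAP, params, effects)
  fe <- fracExcretion(MAP, sig, y[["ALD"]], params, effects)
  out <- list(
    SBP = fast[["SBP"]], DBP = fast[["DBP"]], MAP = MAP, HR = fast[["HR"]],
    SV = fast[["SV"]], EDV = fast[["EDV"]], ESV = fast[["ESV"]],
    EF = fast[["EF"]], CO = fast[["CO"]],
    LVEDP = fast[["LVEDP"]], LVPSP = fast[["LVPSP"]],
    RVEDP = fast[["RVEDP"]], RVPSP = fast[["RVPSP"]],
    RVEDV = fast[["RVEDV"]], RVESV = fast[["RVESV"]],
    PAPsys = fast[["PAPsys"]], PAPdia = fast[["PAPdia"]],
    PVR = params$cardiac$PVR,
    SVR = cmd$SVR, E_sa = cmd$E_sa,
    GFR = haem$GFR, RBF = haem$RBF, RVR = haem$RVR,
    R_aff = haem$R_aff_dyn, R_eff = haem$R_eff_dyn,
    d_aff = haem$d_aff, d_eff = haem$d_eff, P_glom = haem$P_glom,
    PRA = y[["PRA"]] * effects[["renin_activity"]],
    AngI = y[["AngI"]], AngII = y[["AngII"]], ALD = y[["ALD"]],
    AT1_signal = at1,
    Na_conc = y[["Na_total"]] / y[["V_ecf"]],
    Na_total = y[["Na_total"]],
    V_ecf = y[["V_ecf"]], V_blood = params$volume$bv_frac * y[["V_ecf"]],
    frac_excretion = fe, phi_sodin = params$sodium$phi_sodin,
    contractility = cmd$contractility
  )
  structure(out, class = "equilibriumSummary",
            volumes = run$state$circulation,
            pra_state = y[["PRA"]],
            time = run$time, equilibrium = run$equilibrium)
}

#' Simulate the coupled model to its equilibrium
#'
#' Runs the agent-based co-simulation from an initial state until two
#' consecutive comparison windows agree for every exchanged variable, then
#' reports the full physiological summary. Deterministic for fixed
#' parameters, initial state and schedule.
#'
#' @param params model parameters.
#' @param effects named effect multipliers.
#' @param init initial `equilibriumSummary` (e.g. the untreated baseline).
#'   Defaults to the algebraic steady state of `params` with no drug.
#' @param horizon simulation horizon in model days.
#' @param tol equilibrium window tolerance (relative).
#' @param interval exchange interval in model minutes.
#' @param window equilibrium comparison window in model minutes.
#' @param require_equilibrium if `TRUE` (default) a run that hits the
#'   horizon without settling raises a convergence error carrying
#'   diagnostics; if `FALSE` the horizon state is summarised.
#' @return an `equilibriumSummary`; attribute `time` holds the model time
#'   (minutes) at which the equilibrium was detected, attribute `run` the
#'   co-simulation result.
#' @export
simulateToEquilibrium <- function(params, effects = neutralEffects(),
                                  init = NULL, horizon = 14, tol = 1e-3,
                                  interval = 2, window = 30,
                                  require_equilibrium = TRUE) {
  effects <- asEffects(effects)
  if (is.null(init)) init <- steadyState(params)
  agents <- makeCardioRenalAgents(params, effects, init)
  flux_tol <- 1e-3 * max(params$sodium$phi_sodin, 1e-3)
  schedule <- exchangeSchedule(interval = interval,
                               horizon = horizon * 24 * 60,
                               stop_on_equilibrium = TRUE,
                               eq_window = window, eq_tol = tol,
                               eq_check = function(row) {
                                 abs(row[["Na_imbalance"]]) < flux_tol
                               })
  run <- runCosimulation(agents, schedule)
  if (!run$equilibrium && require_equilibrium) {
    tail <- run$trajectory[nrow(run$trajectory), ]
    stopTyped("convergenceError",
              sprintf(paste0("no equilibrium within %g model-days ",
                             "(final SBP %.1f, V_ecf %.2f L)"),
                      horizon, tail[["SBP"]], tail[["V_ecf"]]),
              trajectory_tail = tail)
  }
  out <- summaryFromCosim(run, params, effects)
  attr(out, "run") <- run
  out
}

#' Sodium-loading acceptance test
#'
#' Raises the sodium intake from the patient's normal value (which must lie
#' in 0.028-0.209 mEq/min) to an elevated level and follows the model to its
#' new equilibrium. The patient passes if a new equilibrium is reached with a
#' systolic rise of at most 25 mmHg; failure to converge is the model's
#' pulmonary-congestion analogue and also fails the test.
#'
#' @param patient a `virtualPatient` or a `raasimParams` object.
#' @param elevated_intake elevated sodium intake (mEq/min).
#' @param horizon follow-up horizon in model days.
#' @param ... passed to [simulateToEquilibrium()].
#' @return list with `pass`, `delta_SBP` (mmHg), `converged`, and the new
#'   `summary` (NULL if the run did not converge).
#' @export
sodiumLoadTest <- function(patient, elevated_intake = 0.243, horizon = 10,
                           ...) {
  params <- if (inherits(patient, "virtualPatient")) patient$params else patient
  baseline <- if (inherits(patient, "virtualPatient")) patient$baseline
              else steadyState(params)
  phi0 <- params$sodium$phi_sodin
  if (phi0 < 0.028 || phi0 > 0.209) {
    stopTyped("invalidArgument",
              "baseline sodium intake must lie in [0.028, 0.209] mEq/min")
  }
  if (abs(elevated_intake - phi0) < 1e-12) {
    return(list(pass = TRUE, delta_SBP = 0, converged = TRUE,
                summary = baseline))
  }
  loaded <- params
  loaded$sodium$phi_sodin <- elevated_intake
  res <- tryCatch(
    simulateToEquilibrium(loaded, init = baseline, horizon = horizon, ...),
    convergenceError = function(e) e
  )
  if (inherits(res, "convergenceError")) {
    return(list(pass = FALSE, delta_SBP = NA_real_, converged = FALSE,
                summary = NULL))
  }
  delta <- res$SBP - baseline$SBP
  list(pass = delta <= 25, delta_SBP = delta, converged = TRUE,
       summary = res)
}
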