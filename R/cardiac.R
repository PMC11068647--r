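#' Settled cardiac-cycle summary from the fast circulatory agent
#'
#' Integrates the six-compartment time-varying-elastance circulation (left and
#' right ventricle, systemic arteries and veins, pulmonary arteries and veins,
#' ideal diode valves) at a fixed heart rate until beat-to-beat periodicity,
#' and summarises one settled cycle. This is the "fast agent" of the hybrid
#' model: it works in seconds while the renal/hormonal agent works in minutes.
#'
#' @param params model parameters, see [defaultParameters()].
#' @param V_blood total blood volume (L) imposed by the slow agent.
#' @param hr_command commanded heart rate (beats/min).
#' @param contractility_factor multiplies end-systolic ventricular elastance
#'   (1 = nominal contractility).
#' @param SVR systemic vascular resistance (s*mmHg/mL).
#' @param E_sa systemic arterial elasticity (mmHg/mL).
#' @param init optional vector of 6 compartment volumes (mL) used as a warm
#'   start; total volume is reconciled with `V_blood` through the venous pool.
#' @param tol relative beat-to-beat tolerance on (SBP, DBP, LV SV, RV SV).
#' @param max_cycles cycle budget before a convergence error is raised.
#' @param n_samples if > 0, also return `n_samples` within-cycle samples of
#'   pressures and ventricular volumes (used by the constraint penalty).
#'
#' @return an object of class `cardiacSummary`: a named list with SBP, DBP,
#'   MAP, HR, SV, EDV, ESV, EF, CO (mL/s), LVEDP, LVPSP, RVEDP, RVPSP, RVEDV,
#'   RVESV, PAPsys, PAPdia, mean venous pressures, plus attributes `volumes`
#'   (final state for warm restarts), `cycles` and `samples`.
#'
#' @details Ventricular pressure is `E(t) * (V - V0)` with
#'   `E(t) = Ed + (Es*contractility - Ed) * a(t)` and a raised-cosine
#'   activation over the systolic interval; diastole is the remainder of the
#'   cycle (the systole/diastole transition is the model's discrete phase
#'   event). The Frank-Starling behaviour - higher filling volume giving
#'   higher end-diastolic and stroke volume at fixed contractility - is an
#'   emergent property of this formulation and is checked by the test suite.
#' @export
cardiacCycleSummary <- function(params, V_blood, hr_command,
                                contractility_factor = 1,
                                SVR = params$vascular$SVR0,
                                E_sa = params$cardiac$E_sa0,
                                init = NULL, tol = 1e-4, max_cycles = 60L,
                                n_samples = 0L, dt = params$cardiac$dt) {
  assertPositive(c(V_blood, hr_command, contractility_factor, SVR, E_sa),
                 "cardiac inputs")
  cp <- params$cardiac
  T <- 60 / hr_command
  Tsys <- min(cp$Ts_coef * sqrt(T), 0.5 * T)
  parvec <- c(T, Tsys,
              cp$Ed_lv, cp$Es_lv * contractility_factor * cp$Es_scale,
              cp$Ed_rv, cp$Es_rv * contractility_factor * cp$Es_scale,
              E_sa, cp$E_sv, cp$E_pa, cp$E_pv,
              cp$V0_lv, cp$V0_sa, cp$V0_sv, cp$V0_rv, cp$V0_pa, cp$V0_pv,
              cp$R_mv, cp$R_av, cp$R_tv, cp$R_puv,
              SVR, cp$PVR)
  Vtot <- 1000 * V_blood
  if (is.null(init)) {
    V0 <- c(cp$V0_lv, cp$V0_sa, cp$V0_sv, cp$V0_rv, cp$V0_pa, cp$V0_pv)
    stressed <- Vtot - sum(V0)
    if (stressed <= 0) {
      stopTyped("invalidArgument", "blood volume below total unstressed volume")
    }
    compl <- c(1 / cp$Ed_lv, 1 / E_sa, 1 / cp$E_sv, 1 / cp$Ed_rv,
               1 / cp$E_pa, 1 / cp$E_pv)
    init <- V0 + stressed * compl / sum(compl)
  } else {
    init[3] <- init[3] + (Vtot - sum(init))  # reconcile through venous pool
    if (init[3] <= cp$V0_sv * 0.2) {
      stopTyped("invalidState", "venous pool collapsed while reconciling volume")
    }
  }
  res <- .cardiacRunCpp(as.numeric(init), parvec, dt = dt,
                        maxCycles = as.integer(max_cycles), tol = tol,
                        nSamples = as.integer(n_samples))
  if (!res$converged) {
    stopTyped("convergenceError",
              sprintf("cardiac agent not periodic within %d cycles", max_cycles))
  }
  out <- as.list(res$summary)
  structure(out, class = "cardiacSummary",
            volumes = res$volumes, cycles = res$cycles,
            samples = if (n_samples > 0) res$samples else NULL)
}

#' Left-ventricular ejection fraction
#'
#' @param SV stroke volume (mL), `0 <= SV <= EDV`.
#' @param EDV end-diastolic volume (mL), must be positive.
#' @return ejection fraction in percent, `100 * SV / EDV`.
#' @examples
#' ejectionFraction(70, 100)
#' @export
ejectionFraction <- function(SV, EDV) {
  if (!is.numeric(EDV) || any(!is.finite(EDV)) || any(EDV <= 0)) {
    stopTyped("invalidArgument", "EDV must be positive")
  }
  if (!is.numeric(SV) || any(!is.finite(SV)) || any(SV < 0) || any(SV > EDV)) {
    stopTyped("invalidArgument", "SV must satisfy 0 <= SV <= EDV")
  }
  100 * SV / EDV
}

#' @export
print.cardiacSummary <- function(x, ...) {
  cat("Settled cardiac cycle (", attr(x, "cycles"), " beats to periodicity)\n",
      sep = "")
  cat(sprintf("  BP %.1f/%.1f mmHg (MAP %.1f), HR %.1f bpm\n",
              x$SBP, x$DBP, x$MAP, x$HR))
  cat(sprintf("  LV: SV %.1f mL, EDV %.1f, ESV %.1f, EF %.1f%%\n",
              x$SV, x$EDV, x$ESV, x$EF))
  cat(sprintf("  RV: %.1f/%.1f mmHg, PA %.1f/%.1f mmHg\n",
              x$RVPSP, x$RVEDP, x$PAPsys, x$PAPdia))
  invisible(x)
}
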