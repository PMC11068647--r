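# Algebraic equilibrium of the coupled model. The same closures used by the
# dynamic agents (raas.R, renal.R) are evaluated at their fixed points, so
# the steady state found here is exactly the stationary point of the
# co-simulated dynamics.

# Effective autonomic/vascular commands for a given hormonal and pressure
# state. The baroreflex references the patient's own set point.
vascularCommands <- function(sig, MAP, params, effects) {
  b <- params$baro
  # autonomic commands saturate at physiological extremes
  list(
    SVR = params$vascular$SVR0 *
      exp(params$vascular$g_svr * clampSigma(sig, params)) *
      effects[["vascular_tone"]],
    HR = min(180, max(40, params$cardiac$HR0 * (b$MAP_ref / MAP)^b$g_hr)) *
      effects[["heart_rate"]],
    contractility = min(3, max(0.3,
      params$cardiac$c0 * (b$MAP_ref / MAP)^b$g_c)) *
      effects[["contractility"]],
    E_sa = params$cardiac$E_sa0 * effects[["arterial_elastance"]]
  )
}

# Hormonal fixed point at fixed extracellular volume. Renin secretion
# depends on the AT1 stimulus and on volume only, so given V_ecf the Ang II
# fixed point is a scalar root problem (solved in log space; the mapping is
# monotone, giving a unique fixed point).
solveHormones <- function(V_ecf, params, effects, guess = NULL) {
  r <- params$raas
  cr <- conversionRates(params, effects)
  gain <- r$k_prod * effects[["renin_activity"]] * cr$total /
    ((cr$total + r$k_degI) * r$k_degII)   # AngII per unit renin state
  g <- function(logA) {
    A <- exp(logA)
    sig <- at1Sigma(at1Signal(A, params, effects), params)
    log(gain * reninSecretion(sig, V_ecf, params, effects)) - logA
  }
  lo <- log(1e-4); hi <- log(1e3)
  if (!is.null(guess) && is.finite(guess) && guess > 0) {
    l <- log(guess)
    if (g(l) > 0) { lo <- l } else { hi <- l }
  }
  root <- stats::uniroot(g, c(lo, hi), tol = 1e-10)
  AngII <- exp(root$root)
  sig <- at1Sigma(at1Signal(AngII, params, effects), params)
  PRC <- reninSecretion(sig, V_ecf, params, effects)
  PRA_eff <- PRC * effects[["renin_activity"]]
  AngI <- r$k_prod * PRA_eff / (cr$total + r$k_degI)
  list(AngII = AngII, AngI = AngI, PRC = PRC, PRA_reported = PRA_eff,
       sig = sig)
}

# Hormone/cardiac fixed point at a fixed extracellular volume.
# Returns the consistent (AngII, MAP, cardiac summary, commands) set and the
# sodium-balance residual (intake minus excretion, mEq/min).
innerEquilibrium <- function(V_ecf, params, effects, warm = NULL,
                             tol = 1e-6, max_iter = 120L,
                             cardiac_tol = 1e-5, dt = params$cardiac$dt) {
  r <- params$raas
  V_blood <- params$volume$bv_frac * V_ecf
  horm <- solveHormones(V_ecf, params, effects, guess = warm$AngII)
  AngII <- horm$AngII
  AngI <- horm$AngI
  PRC <- horm$PRC
  PRA_eff <- horm$PRA_reported
  sig <- horm$sig
  MAP <- if (!is.null(warm$MAP)) warm$MAP else params$baro$MAP_ref
  vols <- warm$volumes
  card <- NULL
  for (i in seq_len(max_iter)) {
    cmd <- vascularCommands(sig, MAP, params, effects)
    card <- cardiacCycleSummary(params, V_blood, cmd$HR, cmd$contractility,
                                cmd$SVR, cmd$E_sa, init = vols,
                                tol = cardiac_tol, dt = dt)
    vols <- attr(card, "volumes")
    MAP_new <- card$MAP
    dM <- abs(MAP_new - MAP) / MAP
    MAP <- MAP + 0.7 * (MAP_new - MAP)
    if (dM < tol) break
  }
  if (i == max_iter && dM >= tol * 10) {
    stopTyped("convergenceError", "hormone/cardiac fixed point did not settle")
  }
  ALD <- aldosteroneTarget(sig, params)
  haem <- renalHaemodynamics(sig, MAP, params, effects)
  fe <- fracExcretion(MAP, sig, ALD, params, effects)
  excretion <- haem$GFR / 1000 * params$sodium$Na_ref * fe
  list(AngII = AngII, AngI = AngI, PRC = PRC, PRA_reported = PRA_eff,
       ALD = ALD, sig = sig, MAP = MAP, card = card, cmd = cmd, haem = haem,
       fe = fe, excretion = excretion,
       residual = params$sodium$phi_sodin - excretion,
       volumes = vols, V_blood = V_blood)
}

#' Equilibrium of the reduced cardiorenal model
#'
#' Solves the coupled fixed point of the fast circulation and the slow
#' renal/hormonal agent: extracellular volume is found by bisection on the
#' sodium balance (intake = excretion at the sodium set point), with the
#' hormone chain and the settled cardiac cycle made self-consistent at every
#' trial volume. Because the solver evaluates the same algebra as the
#' dynamic right-hand sides, its output is the stationary state of
#' [simulateToEquilibrium()] for the same parameters and multipliers.
#'
#' @param params model parameters ([defaultParameters()]).
#' @param effects named effect multipliers (default: no drug).
#' @param precision `"fine"` (default) or `"coarse"`; coarse mode relaxes the
#'   inner tolerances and is used inside optimisation loops.
#' @param warm optional warm start (a previous return value).
#' @return an `equilibriumSummary` object: named list of the reported
#'   physiological variables (pressures, ventricular volumes, renal and
#'   intraglomerular haemodynamics, RAAS biomarkers, sodium/volume state).
#' @export
steadyState <- function(params, effects = neutralEffects(),
                        precision = c("fine", "coarse"), warm = NULL) {
  precision <- match.arg(precision)
  effects <- asEffects(effects)
  if (inherits(warm, "equilibriumSummary")) {
    warm <- list(AngII = warm$AngII, MAP = warm$MAP,
                 volumes = attr(warm, "volumes"), V_ecf = warm$V_ecf)
  }
  inner_tol <- if (precision == "fine") 1e-7 else 1e-4
  card_tol <- if (precision == "fine") 1e-6 else 1e-4
  dt <- if (precision == "fine") params$cardiac$dt else 4 * params$cardiac$dt
  resid_tol <- (if (precision == "fine") 1e-6 else 1e-3) *
    max(params$sodium$phi_sodin, 1e-3)

  warmEnv <- new.env(parent = emptyenv())
  warmEnv$w <- warm
  warmEnv$evals <- 0L
  f <- function(V) {
    warmEnv$evals <- warmEnv$evals + 1L
    res <- innerEquilibrium(V, params, effects, warm = warmEnv$w,
                            tol = inner_tol, cardiac_tol = card_tol, dt = dt)
    warmEnv$w <- list(AngII = res$AngII, MAP = res$MAP,
                      volumes = res$volumes)
    warmEnv$last <- res
    res$residual
  }
  Vref <- params$volume$V_ecf_ref
  cp <- params$cardiac
  V0tot <- (cp$V0_lv + cp$V0_sa + cp$V0_sv + cp$V0_rv + cp$V0_pa +
              cp$V0_pv) / 1000                      # L blood, unstressed
  Vmin <- 1.02 * V0tot / params$volume$bv_frac      # ECF giving any filling
  Vmax <- 2.0 * Vref

  # warm-started safeguarded secant on the sodium-balance residual
  # (monotone decreasing in volume); bracket grown on demand
  x0 <- if (!is.null(warm) && !is.null(warm$V_ecf)) warm$V_ecf else Vref
  x0 <- min(max(x0, Vmin), Vmax)
  f0 <- f(x0)
  x1 <- min(max(x0 * (if (f0 > 0) 1.01 else 0.99), Vmin), Vmax)
  f1 <- f(x1)
  lo <- NA_real_; hi <- NA_real_; flo <- NA_real_
  setBracket <- function(x, fx) {
    if (fx > 0) { if (is.na(lo) || x > lo) { lo <<- x; flo <<- fx } }
    else if (is.na(hi) || x < hi) hi <<- x
  }
  setBracket(x0, f0); setBracket(x1, f1)
  best <- if (abs(f1) < abs(f0)) list(x = x1, fx = f1) else list(x = x0, fx = f0)
  iter <- 0L
  while (abs(best$fx) > resid_tol && iter < 60L) {
    iter <- iter + 1L
    step <- if (abs(f1 - f0) > 1e-14) (x1 - x0) * f1 / (f1 - f0) else NA_real_
    x2 <- x1 - step
    inBracket <- !is.na(lo) && !is.na(hi)
    if (!is.finite(x2) ||
        (inBracket && (x2 <= min(lo, hi) || x2 >= max(lo, hi))) ||
        x2 < Vmin || x2 > Vmax) {
      if (inBracket) {
        x2 <- 0.5 * (lo + hi)
      } else if (!is.na(lo)) {
        x2 <- min(Vmax, lo * 1.1)
        if (x2 >= Vmax && flo > resid_tol && lo >= Vmax) break
      } else {
        x2 <- max(Vmin, hi * 0.9)
      }
    }
    if (abs(x2 - x1) < 1e-10) break
    f2 <- f(x2)
    setBracket(x2, f2)
    x0 <- x1; f0 <- f1; x1 <- x2; f1 <- f2
    if (abs(f2) < abs(best$fx)) best <- list(x = x2, fx = f2)
    if ((is.na(lo) && x1 <= Vmin + 1e-9) || (is.na(hi) && x1 >= Vmax - 1e-9)) {
      break  # residual one-signed over the whole admissible range
    }
  }
  if (abs(best$fx) > max(resid_tol, 1e-3 * max(params$sodium$phi_sodin, 1e-3))) {
    stopTyped("convergenceError",
              "sodium balance cannot be closed within the volume range")
  }
  res <- if (identical(best$x, x1)) warmEnv$last else {
    f(best$x); warmEnv$last
  }
  out <- assembleEquilibrium(best$x, res, params, effects)
  attr(out, "evals") <- warmEnv$evals
  out
}

assembleEquilibrium <- function(V_ecf, res, params, effects) {
  card <- res$card
  haem <- res$haem
  out <- list(
    SBP = card$SBP, DBP = card$DBP, MAP = card$MAP, HR = card$HR,
    SV = card$SV, EDV = card$EDV, ESV = card$ESV, EF = card$EF,
    CO = card$CO,
    LVEDP = card$LVEDP, LVPSP = card$LVPSP,
    RVEDP = card$RVEDP, RVPSP = card$RVPSP,
    RVEDV = card$RVEDV, RVESV = card$RVESV,
    PAPsys = card$PAPsys, PAPdia = card$PAPdia,
    PVR = params$cardiac$PVR,
    SVR = res$cmd$SVR, E_sa = res$cmd$E_sa,
    GFR = haem$GFR, RBF = haem$RBF, RVR = haem$RVR,
    R_aff = haem$R_aff_dyn, R_eff = haem$R_eff_dyn,
    d_aff = haem$d_aff, d_eff = haem$d_eff, P_glom = haem$P_glom,
    PRA = res$PRA_reported, AngI = res$AngI, AngII = res$AngII,
    ALD = res$ALD,
    AT1_signal = at1Signal(res$AngII, params, effects),
    Na_conc = params$sodium$Na_ref,
    Na_total = params$sodium$Na_ref * V_ecf,
    V_ecf = V_ecf, V_blood = res$V_blood,
    frac_excretion = res$fe, phi_sodin = params$sodium$phi_sodin,
    contractility = res$cmd$contractility
  )
  structure(out, class = "equilibriumSummary",
            volumes = res$volumes, residual = res$residual,
            pra_state = res$PRC)
}

#' @export
print.equilibriumSummary <- function(x, ...) {
  cat("Model equilibrium\n")
  cat(sprintf("  BP %.1f/%.1f mmHg (MAP %.1f), HR %.1f, SV %.1f mL, EF %.1f%%\n",
              x$SBP, x$DBP, x$MAP, x$HR, x$SV, x$EF))
  cat(sprintf("  GFR %.1f mL/min, RBF %.2f L/min, P_glom %.1f mmHg\n",
              x$GFR, x$RBF, x$P_glom))
  cat(sprintf("  PRA %.1f fmol/mL/min, AngI %.1f, AngII %.2f fmol/mL, ALD %.0f pg/mL\n",
              x$PRA, x$AngI, x$AngII, x$ALD))
  cat(sprintf("  V_ecf %.2f L, blood %.2f L, sodium intake %.3f mEq/min\n",
              x$V_ecf, x$V_blood, x$phi_sodin))
  invisible(x)
}
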