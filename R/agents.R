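# Concrete wiring of the two model agents: the fast circulation (seconds)
# and the slow renal/hormonal/fluid agent (minutes).

# Inlined right-hand side of the slow agent. Algebraically identical to
# composing raasDerivatives() and renalUpdate() (asserted by the test
# suite), but avoids their per-call validation inside the ODE solver.
# State order: PRA, AngI, AngII, ALD, Na_total, V_ecf.
makeSlowRHS <- function(params, effects) {
  r <- params$raas
  sd <- params$sodium
  cr <- conversionRates(params, effects)
  fact <- effects[["renin_activity"]]
  function(t, y, parms) {
    y <- pmax(y, 0)  # clip negative concentrations (flagged upstream)
    MAP <- parms$MAP
    sig <- at1Sigma(y[[3]] * effects[["at1_receptor"]] *
                      params$raas$at1_gain, params)
    conv <- cr$total * y[[2]]
    h <- renalHaemodynamics(sig, MAP, params, effects)
    Na_conc <- y[[5]] / y[[6]]
    fe <- fracExcretion(MAP, sig, y[[4]], params, effects)
    list(c(
      (reninSecretion(sig, y[[6]], params, effects) - y[[1]]) / r$tau_renin,
      r$k_prod * y[[1]] * fact - conv - r$k_degI * y[[2]],
      conv - r$k_degII * y[[3]],
      (aldosteroneTarget(sig, params) - y[[4]]) / r$tau_ald,
      sd$phi_sodin - h$GFR / 1000 * Na_conc * fe,
      sd$g_osm * (Na_conc - sd$Na_ref)
    ))
  }
}

#' Build the fast/slow agent pair of the cardiorenal model
#'
#' @param params model parameters.
#' @param effects named effect multipliers (drug state held fixed during the
#'   run; treatment switches build a fresh pair).
#' @param init an `equilibriumSummary` (typically the patient baseline) that
#'   seeds both agents and the initial exchange values.
#' @param rtol,atol slow-agent solver tolerances.
#' @return list of two [agentSpec()] objects (`circulation`, `renal`).
#' @export
makeCardioRenalAgents <- function(params, effects = neutralEffects(),
                                  init, rtol = 1e-6, atol = 1e-9) {
  effects <- asEffects(effects)
  if (!inherits(init, "equilibriumSummary")) {
    stopTyped("invalidArgument", "init must be an equilibriumSummary")
  }
  negWarned <- new.env(parent = emptyenv()); negWarned$done <- FALSE

  # the stored renin STATE is the pre-inhibition activity; the reported PRA
  # applies the renin_activity multiplier of the run that produced it
  pra0 <- if (!is.null(attr(init, "pra_state"))) attr(init, "pra_state") else init$PRA
  slowInit <- c(PRA = pra0,
                AngI = init$AngI, AngII = init$AngII, ALD = init$ALD,
                Na_total = init$Na_total, V_ecf = init$V_ecf)

  rhs <- makeSlowRHS(params, effects)
  slowStep <- function(state, imports, t0, t1) {
    MAP <- imports[["MAP"]]
    sol <- deSolve::lsoda(y = state, times = c(t0, t1), func = rhs,
                          parms = list(MAP = MAP),
                          rtol = rtol, atol = atol)
    y <- sol[nrow(sol), -1]
    if (any(y[c("PRA", "AngI", "AngII", "ALD")] < 0)) {
      if (!negWarned$done) {
        warning("negative hormone concentration clipped to 0", call. = FALSE)
        negWarned$done <- TRUE
      }
      y <- pmax(y, 0)
    }
    sig <- at1Sigma(at1Signal(y[["AngII"]], params, effects), params)
    cmd <- vascularCommands(sig, MAP, params, effects)
    ru <- renalUpdate(list(Na_total = y[["Na_total"]], V_ecf = y[["V_ecf"]]),
                      MAP, at1Signal(y[["AngII"]], params, effects), effects,
                      params, ALD = y[["ALD"]])
    exports <- c(V_blood = params$volume$bv_frac * y[["V_ecf"]],
                 SVR = cmd$SVR, HR = cmd$HR,
                 contractility = cmd$contractility, E_sa = cmd$E_sa,
                 PRA_rep = y[["PRA"]] * effects[["renin_activity"]],
                 AngI = y[["AngI"]], AngII = y[["AngII"]], ALD = y[["ALD"]],
                 Na_total = y[["Na_total"]], V_ecf = y[["V_ecf"]],
                 Na_imbalance = ru$derivatives[["dNa_total"]])
    list(state = y, exports = exports)
  }

  fastStep <- function(state, imports, t0, t1) {
    card <- cardiacCycleSummary(params,
                                V_blood = imports[["V_blood"]],
                                hr_command = imports[["HR"]],
                                contractility_factor = imports[["contractility"]],
                                SVR = imports[["SVR"]],
                                E_sa = imports[["E_sa"]],
                                init = state, tol = 1e-4,
                                dt = 2 * params$cardiac$dt)
    list(state = attr(card, "volumes"),
         exports = unlist(card[c("MAP", "SBP", "DBP", "SV", "EDV", "ESV",
                                 "EF", "CO", "LVEDP", "LVPSP", "RVEDP",
                                 "RVPSP", "RVEDV", "RVESV", "PAPsys",
                                 "PAPdia")]))
  }

  sig0 <- at1Sigma(at1Signal(slowInit[["AngII"]], params, effects), params)
  cmd0 <- vascularCommands(sig0, init$MAP, params, effects)
  slowExports0 <- c(V_blood = params$volume$bv_frac * slowInit[["V_ecf"]],
                    SVR = cmd0$SVR, HR = cmd0$HR,
                    contractility = cmd0$contractility, E_sa = cmd0$E_sa,
                    PRA_rep = slowInit[["PRA"]] * effects[["renin_activity"]],
                    AngI = slowInit[["AngI"]], AngII = slowInit[["AngII"]],
                    ALD = slowInit[["ALD"]], Na_total = slowInit[["Na_total"]],
                    V_ecf = slowInit[["V_ecf"]],
                    Na_imbalance = 0)
  fastExports0 <- unlist(init[c("MAP", "SBP", "DBP", "SV", "EDV", "ESV",
                                "EF", "CO", "LVEDP", "LVPSP", "RVEDP",
                                "RVPSP", "RVEDV", "RVESV", "PAPsys",
                                "PAPdia")])

  circulation <- agentSpec(
    name = "circulation",
    state = attr(init, "volumes"),
    unit = "s",
    step = fastStep,
    exports = names(fastExports0),
    imports = c("V_blood", "SVR", "HR", "contractility", "E_sa"),
    freeze_tol = 1e-4
  )
  circulation$init_exports <- fastExports0
  renal <- agentSpec(
    name = "renal",
    state = slowInit,
    unit = "min",
    step = slowStep,
    exports = names(slowExports0),
    imports = "MAP",
    freeze_tol = 0  # the slow agent always integrates
  )
  renal$init_exports <- slowExports0
  list(circulation = circulation, renal = renal)
}
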