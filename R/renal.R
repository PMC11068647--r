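# Ohmic renal haemodynamics with Poiseuille diameter closure, plus the
# sodium/volume balance of the slow agent.

# Arteriolar tone, exponential in the AT1 occupancy signal (bounded because
# sigma is bounded): both vessels constrict directly with AT1 (efferent
# sensitivity > afferent >= 0); the afferent additionally dilates through the
# tubuloglomerular-feedback term (g_tgf > g_aff), so its NET response to a
# rising AT1 signal is dilatory, and it constricts with arterial pressure
# through the myogenic exponent.
renalHaemodynamics <- function(sig, MAP, params, effects) {
  rn <- params$renal
  assertPositive(MAP, "MAP")
  # the arteriolar occupancy signal saturates (finite receptor/tubular range)
  ds <- clampSigma(sig, params)
  R_aff <- rn$Ra0 * exp((rn$g_aff - rn$g_tgf) * ds) *
    (MAP / params$sodium$MAP_ref_fe)^rn$g_myo * effects[["afferent_tone"]]
  R_eff <- rn$Re0 * exp(rn$g_eff * ds)
  RVR <- R_aff + R_eff + rn$R_rest
  RBF <- (MAP - rn$P_ven) / RVR                   # L/min
  P_glom <- MAP - RBF * R_aff
  net <- P_glom - rn$P_bowman_onc
  GFR <- rn$Kf * max(0, net)                      # mL/min
  list(
    R_aff = R_aff, R_eff = R_eff, RVR = RVR, RBF = RBF,
    P_glom = P_glom, GFR = GFR,
    negative_filtration = net < 0,
    R_aff_dyn = R_aff * rn$dyn_per_mmHgminL,
    R_eff_dyn = R_eff * rn$dyn_per_mmHgminL,
    d_aff = rn$d_aff0 * (rn$Ra0 / R_aff)^0.25,
    d_eff = rn$d_eff0 * (rn$Re0 / R_eff)^0.25
  )
}

# Fraction of the filtered sodium load that is excreted. Rises steeply with
# arterial pressure (pressure natriuresis) and falls with AT1 occupancy and
# aldosterone; thiazide action multiplies the tubular reabsorption fraction,
# i.e. fe_total = 1 - (1 - fe_hormonal) * F_reabsorption.
fracExcretion <- function(MAP, sig, ALD, params, effects) {
  sd <- params$sodium
  fe <- sd$fe0 * (MAP / sd$MAP_ref_fe)^sd$g_pn *
    exp(-sd$h_at1 * clampSigma(sig, params)) *
    (ALD / params$raas$ALD0)^(-sd$h_ald)
  fe <- min(max(fe, 1e-6), 0.5)
  fe_total <- 1 - (1 - fe) * effects[["sodium_reabsorption"]]
  min(max(fe_total, 1e-6), 0.5)
}

#' Renal and fluid-balance update of the slow agent
#'
#' Computes arteriolar resistances, renal blood flow, glomerular pressure,
#' filtration rate and the sodium/volume derivatives for a given arterial
#' pressure and AT1 stimulus. Resistances respond to the AT1 signal with a
#' direct constriction (efferent sensitivity greater than afferent) plus a
#' tubuloglomerular dilation of the afferent vessel, and to pressure through
#' a myogenic term; `RBF = (MAP - P_ven) / (R_aff + R_eff + R_rest)`;
#' `P_glom = MAP - RBF * R_aff`; `GFR = Kf * (P_glom - P_bowman_onc)` clamped
#' at zero (with a flag) if net filtration pressure turns negative.
#' Arteriolar diameters follow the Poiseuille closure `d ~ R^(-1/4)`.
#'
#' @param state list or named vector with `Na_total` (mEq) and `V_ecf` (L).
#' @param MAP mean arterial pressure (mmHg).
#' @param at1_signal AT1 receptor stimulus (fmol/mL Ang II equivalents,
#'   already subject to any receptor blockade).
#' @param effects named effect multipliers.
#' @param params model parameters.
#' @param ALD plasma aldosterone (pg/mL) entering sodium reabsorption.
#' @return list with `derivatives` (`dNa_total`, `dV_ecf`, per minute) and
#'   `renal`, a summary containing resistances (whole-kidney mmHg*min/L and
#'   reported dyn*s/cm^5), diameters (um), `RBF` (L/min), `P_glom` (mmHg),
#'   `GFR` (mL/min), fractional excretion, sodium excretion (mEq/min) and
#'   plasma sodium concentration (mEq/L).
#' @export
renalUpdate <- function(state, MAP, at1_signal, effects = neutralEffects(),
                        params = defaultParameters(),
                        ALD = params$raas$ALD0) {
  effects <- asEffects(effects)
  st <- as.list(state)
  assertPositive(c(st$Na_total, st$V_ecf), "sodium/volume state")
  sig <- at1Sigma(at1_signal, params)
  h <- renalHaemodynamics(sig, MAP, params, effects)
  Na_conc <- st$Na_total / st$V_ecf
  fe <- fracExcretion(MAP, sig, ALD, params, effects)
  excretion <- h$GFR / 1000 * Na_conc * fe        # mEq/min
  dNa <- params$sodium$phi_sodin - excretion
  dV <- params$sodium$g_osm * (Na_conc - params$sodium$Na_ref)
  list(
    derivatives = c(dNa_total = dNa, dV_ecf = dV),
    renal = c(h[c("R_aff", "R_eff", "RVR", "RBF", "P_glom", "GFR",
                  "R_aff_dyn", "R_eff_dyn", "d_aff", "d_eff",
                  "negative_filtration")],
              list(frac_excretion = fe, excretion = excretion,
                   Na_conc = Na_conc))
  )
}
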