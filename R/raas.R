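#' Share of Ang I -> Ang II conversion carried by ACE
#'
#' With two parallel first-order conversion routes, the fraction of total
#' angiotensin II formation attributable to ACE is
#' `100 * cACE / (cACE + cchym)` percent.
#'
#' @param cACE ACE activity (1/h), non-negative.
#' @param cchym chymase activity (1/h), positive.
#' @return percent contribution of ACE.
#' @examples
#' aceContributionFraction(54.1, 1.1) # about 98
#' aceContributionFraction(8.9, 1.1)  # about 89
#' @export
aceContributionFraction <- function(cACE, cchym) {
  assertFiniteNonNegative(cACE, "cACE")
  assertPositive(cchym, "cchym")
  100 * cACE / (cACE + cchym)
}

#' Genotype-specific ACE activities from a group mean
#'
#' Plasma ACE activity rises by an average of 28% (ID) and 56% (DD) relative
#' to the II genotype. Treating a given activity as the mean of the three
#' genotype values gives `II = 3*mean/(1 + 1.28 + 1.56)`, `ID = 1.28*II`,
#' `DD = 1.56*II`; the three values average back to the input.
#'
#' @param mean_cACE mean ACE activity of the group (1/h), positive.
#' @param digits rounding applied to the returned values (default 1, the
#'   reporting precision); use `NA` for unrounded values.
#' @return named numeric vector `c(II=, ID=, DD=)` in 1/h.
#' @examples
#' genotypeAceActivities(54.1) # 42.3, 54.1, 65.9
#' genotypeAceActivities(8.9)  # 7.0, 8.9, 10.8
#' @export
genotypeAceActivities <- function(mean_cACE, digits = 1) {
  assertPositive(mean_cACE, "mean_cACE")
  ii <- 3 * mean_cACE / (1 + 1.28 + 1.56)
  out <- c(II = ii, ID = 1.28 * ii, DD = 1.56 * ii)
  if (!is.na(digits)) out <- round(out, digits)
  out
}

# ---- internal shared algebra ------------------------------------------------
# The same closures are used by the dynamic right-hand sides and by the
# algebraic steady-state solver, so both share their fixed points exactly.

# AT1 receptor stimulus: receptor-blockade multiplier applied to Ang II,
# scaled by the patient's receptor sensitivity (at1_gain). Patients with a
# blunted receptor pool run higher hormone levels at the same effective
# stimulus, which is what makes baseline RAAS biomarkers predictive of the
# response to RAAS blockade.
at1Signal <- function(AngII, params, effects) {
  AT1 <- AngII * effects[["at1_receptor"]] * params$raas$at1_gain
  pmax(AT1, 0)
}

# Hill-type receptor occupancy/transduction of the AT1 stimulus, in [0, 1).
# Downstream responses are exponential in (sigma - sigma_ref), so they are
# bounded and respond to absolute occupancy changes: equal-ratio Ang II
# changes move the response most in the steep mid-range of the curve and
# little once the receptor pool saturates.
at1Sigma <- function(AT1, params) {
  r <- params$raas
  AT1 <- pmax(AT1, 0)
  AT1^r$n_at1 / (r$K_at1^r$n_at1 + AT1^r$n_at1)
}

sigmaRef <- function(params) at1Sigma(params$raas$AT1_ref, params)

# Effector-side occupancy deviation: vascular smooth muscle and tubular
# transport saturate, so their drive is the occupancy deviation clamped to
# +/- 0.6 around the reference.
clampSigma <- function(sig, params, width = 0.6) {
  min(width, max(-width, sig - sigmaRef(params)))
}

# Renin secretion drive: suppressed by AT1 occupancy and by volume
# expansion, scaled by the sympathetic (beta-receptor) multiplier.
reninSecretion <- function(sig, V_ecf, params, effects) {
  r <- params$raas
  r$R0 * params$scales$R0_scale *
    exp(-r$g_renin_at1 * (sig - sigmaRef(params))) *
    (params$volume$V_ecf_ref / V_ecf)^r$g_renin_vol *
    effects[["renin_secretion"]]
}

aldosteroneTarget <- function(sig, params) {
  params$raas$ALD0 * params$scales$ALD0_scale *
    exp(params$raas$g_ald * (sig - sigmaRef(params)))
}

# rate constants converted to the slow agent's unit (1/min)
conversionRates <- function(params, effects) {
  cACE <- params$rates$cACE / 60 * effects[["ace_activity"]]
  cchym <- params$rates$cchym / 60
  list(cACE = cACE, cchym = cchym, total = cACE + cchym)
}

#' Time derivatives of the circulating RAAS state
#'
#' Right-hand side of the renin-angiotensin-aldosterone subsystem in the slow
#' agent's time unit (minutes). Ang I is produced proportionally to effective
#' plasma renin activity and removed by ACE conversion (subject to the ACE
#' multiplier), chymase conversion and non-specific clearance; Ang II is
#' produced by both conversion routes and cleared first-order; renin relaxes
#' toward a secretion drive under negative AT1 and volume feedback times the
#' sympathetic multiplier; aldosterone relaxes toward an AT1-driven target.
#'
#' Renin inhibition (the `renin_activity` multiplier) scales both the Ang I
#' production flux and the reported plasma renin activity.
#'
#' @param state named vector or list with `PRA` (fmol/mL/min), `AngI`,
#'   `AngII` (fmol/mL) and `ALD` (pg/mL), all non-negative.
#' @param params model parameters ([defaultParameters()]).
#' @param effects named effect multipliers ([neutralEffects()] or the result
#'   of [applyRegimen()]).
#' @param V_ecf extracellular fluid volume (L) seen by the volume feedback;
#'   defaults to the set point.
#' @return named vector of time derivatives (per minute) with attributes
#'   `fluxes` (ACE flux, chymase flux, production flux) and `PRA_reported`.
#' @export
raasDerivatives <- function(state, params, effects = neutralEffects(),
                            V_ecf = params$volume$V_ecf_ref) {
  effects <- asEffects(effects)
  state <- unlist(state)[c("PRA", "AngI", "AngII", "ALD")]
  if (any(!is.finite(state)) || any(state < 0)) {
    stopTyped("invalidState", "RAAS state entries must be finite and non-negative")
  }
  r <- params$raas
  cr <- conversionRates(params, effects)
  fact <- effects[["renin_activity"]]
  PRA_eff <- state[["PRA"]] * fact
  sig <- at1Sigma(at1Signal(state[["AngII"]], params, effects), params)

  prod_AngI <- r$k_prod * PRA_eff
  flux_ace <- cr$cACE * state[["AngI"]]
  flux_chym <- cr$cchym * state[["AngI"]]

  d <- c(
    PRA = (reninSecretion(sig, V_ecf, params, effects) - state[["PRA"]]) / r$tau_renin,
    AngI = prod_AngI - flux_ace - flux_chym - r$k_degI * state[["AngI"]],
    AngII = flux_ace + flux_chym - r$k_degII * state[["AngII"]],
    ALD = (aldosteroneTarget(sig, params) - state[["ALD"]]) / r$tau_ald
  )
  structure(d,
            fluxes = c(ace = unname(flux_ace), chymase = unname(flux_chym),
                       production = unname(prod_AngI)),
            PRA_reported = unname(PRA_eff))
}
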