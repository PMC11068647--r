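#' Rate constants of angiotensin I conversion
#'
#' First-order rate constants for the two parallel Ang I -> Ang II routes:
#' the angiotensin-converting enzyme (ACE) and chymase. Defaults are the
#' model's nominal values, 54.1 1/h for ACE and 1.1 1/h for chymase.
#'
#' @param cACE ACE catalytic activity (1/h).
#' @param cchym chymase catalytic activity (1/h).
#' @return a `rateConstants` list.
#' @export
rateConstants <- function(cACE = 54.1, cchym = 1.1) {
  assertPositive(c(cACE, cchym), "rate constants")
  structure(list(cACE = cACE, cchym = cchym), class = "rateConstants")
}

#' Full parameter set of the reduced cardiorenal model
#'
#' Assembles the parameterisation of the reduced hybrid model: Ang I
#' conversion kinetics, renin/aldosterone regulation, the six-compartment
#' circulation, baroreflex gains, Ohmic renal haemodynamics with a filtration
#' coefficient, and sodium/volume control. Defaults were calibrated once so
#' that the unconstrained baseline (cACE = 54.1 1/h) settles inside the
#' physiological envelopes of the study population (SBP about 154 mmHg, DBP
#' about 100 mmHg, GFR about 93 mL/min, plasma Ang II in the 2-6 fmol/mL band
#' across the ACE-activity range).
#'
#' Patient-level entries (intrinsic heart rate `HR0`, contractility scale
#' `c0`, resting vascular tone `SVR0`, arterial elasticity `E_sa0`, sodium
#' intake `phi_sodin`, excreted filtration fraction `fe0`, blood/extracellular
#' volume ratio `bv_frac`, volume set point `V_ecf_ref`, ventricular stiffness
#' scale `Es_scale`, baroreflex set point `MAP_ref`, hormone scales
#' `R0_scale`, `ALD0_scale`) are the quantities fitted per virtual patient;
#' everything else is shared model structure.
#'
#' @param cACE ACE activity (1/h); 54.1 is the high-activity nominal value.
#' @param cchym chymase activity (1/h).
#' @return an object of class `raasimParams` (nested named lists).
#' @export
defaultParameters <- function(cACE = 54.1, cchym = 1.1) {
  rates <- rateConstants(cACE, cchym)
  p <- list(
    rates = rates,
    raas = list(
      # first-order chain calibrated against the reported subpopulation
      # biomarker means at cACE = 54.1 and 8.9 1/h (all rates per minute)
      k_prod  = 0.975,   # Ang I production per unit plasma renin activity
      k_degI  = 2.714,   # non-conversion Ang I clearance (1/min)
      k_degII = 1.458,   # Ang II clearance (1/min)
      R0      = 31.3,    # renin secretion reference (fmol/mL/min)
      tau_renin = 30,    # renin relaxation time (min)
      ALD0    = 196.3,   # aldosterone reference (pg/mL)
      tau_ald = 60,      # aldosterone relaxation time (min)
      AT1_ref = 5.3,     # reference AT1 stimulus (fmol/mL Ang II equivalents)
      K_at1   = 2.5,     # half-occupancy of the AT1 transduction (fmol/mL)
      n_at1   = 2.5,     # Hill coefficient of the AT1 transduction
      at1_gain = 1,      # patient receptor sensitivity scaling the stimulus
      g_renin_at1 = 1.92, # AT1 occupancy gain on renin secretion
      g_renin_vol = 4,   # volume feedback exponent on renin secretion
      g_ald   = 0.355    # AT1 occupancy gain of the aldosterone target
    ),
    cardiac = list(
      HR0 = 75, c0 = 1,
      Ed_lv = 0.0677, Es_lv = 4.72, Ed_rv = 0.0534, Es_rv = 0.548,
      E_sa0 = 0.9, E_sv = 0.0264, E_pa = 0.1216, E_pv = 0.0362,
      V0_lv = 5, V0_sa = 550, V0_sv = 3183, V0_rv = 10, V0_pa = 60,
      V0_pv = 350,
      R_mv = 0.006, R_av = 0.04, R_tv = 0.005, R_puv = 0.005,
      PVR = 0.097,
      Es_scale = 1,
      Ts_coef = 0.388,    # systolic fraction coefficient: Tsys = 0.388*sqrt(T)
      dt = 2.5e-4         # fast-agent RK4 step (s)
    ),
    vascular = list(
      SVR0 = 1.369,       # s*mmHg/mL at reference AT1 occupancy
      g_svr = 0.8         # AT1 occupancy gain of systemic vascular tone
    ),
    baro = list(
      MAP_ref = 126.08,   # baroreflex set point (mmHg); patient-level
      g_hr = 1.2,         # heart-rate gain
      g_c  = 0.4          # contractility gain
    ),
    renal = list(
      Ra0 = 65.23, Re0 = 32.25, R_rest = 12.5,  # mmHg*min/L (whole kidney)
      g_aff = 0.05,       # direct AT1 constriction, afferent (>= 0)
      g_eff = 0.45,       # direct AT1 constriction, efferent (> afferent)
      g_tgf = 0.45,       # tubuloglomerular-feedback dilation, afferent
      g_myo = 1.0,        # myogenic response to arterial pressure
      Kf = 3.12,          # filtration coefficient (mL/min/mmHg)
      P_bowman_onc = 23.7, # Bowman capsule + oncotic back-pressure (mmHg)
      P_ven = 4,          # renal venous pressure (mmHg)
      d_aff0 = 13.7, d_eff0 = 18.7,  # diameters (um) at reference resistance
      dyn_per_mmHgminL = 80          # unit conversion for reporting
    ),
    sodium = list(
      Na_ref = 143.6,     # plasma sodium set point (mEq/L)
      phi_sodin = 0.1,    # sodium intake (mEq/min); patient-level
      fe0 = NA_real_,     # fractional excretion at reference; solved below
      g_pn = 7,           # pressure-natriuresis exponent
      h_at1 = 2.2,        # AT1 occupancy anti-natriuretic gain
      h_ald = 1.2,        # aldosterone anti-natriuretic exponent
      MAP_ref_fe = 126.08, # renal function curve reference (mmHg)
      g_osm = 0.02        # osmotic volume relaxation (L/min per mEq/L)
    ),
    volume = list(
      V_ecf_ref = 15,     # extracellular fluid volume set point (L)
      bv_frac = 1 / 3     # blood volume as a fraction of ECF volume
    ),
    scales = list(R0_scale = 1, ALD0_scale = 1)
  )
  # fractional excretion at reference closes sodium balance at baseline:
  # fe0 = phi_sodin / (GFR_ref * Na_ref), GFR_ref = 93.6 mL/min
  p$sodium$fe0 <- p$sodium$phi_sodin / (93.6 / 1000 * p$sodium$Na_ref)
  class(p) <- "raasimParams"
  p
}

#' @export
print.raasimParams <- function(x, ...) {
  cat("Reduced cardiorenal model parameters\n")
  cat(sprintf("  cACE %.1f 1/h, cchym %.1f 1/h (ACE share %.1f%%)\n",
              x$rates$cACE, x$rates$cchym,
              aceContributionFraction(x$rates$cACE, x$rates$cchym)))
  cat(sprintf("  HR0 %.0f bpm, SVR0 %.2f s*mmHg/mL, E_sa0 %.2f mmHg/mL\n",
              x$cardiac$HR0, x$vascular$SVR0, x$cardiac$E_sa0))
  cat(sprintf("  sodium intake %.3f mEq/min, ECF set point %.1f L\n",
              x$sodium$phi_sodin, x$volume$V_ecf_ref))
  invisible(x)
}
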