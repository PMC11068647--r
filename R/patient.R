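# Virtual-patient generation: demographic targets -> constrained model fit.

#' Options controlling virtual-patient generation
#'
#' @param lambda,mu,generations,Pf stochastic-ranking evolution strategy
#'   budget used per patient (desk-scale defaults; see [sresOptions()] for
#'   the optimizer's own defaults).
#' @param fit_tol relative tolerance on each fitted target (SBP, DBP, HR,
#'   SV) at acceptance.
#' @param constraints physiological box constraints ([constraintSet()]);
#'   `NULL` uses [defaultConstraints()].
#' @param sodium_horizon,sodium_interval,sodium_window co-simulation settings
#'   of the per-patient sodium-loading test (model days / minutes).
#' @param retry_budget maximum generation attempts per accepted patient.
#' @return a `patientGenOptions` list.
#' @export
patientGenOptions <- function(lambda = 16L, mu = 4L, generations = 8L,
                              Pf = 0.45, fit_tol = 0.02, constraints = NULL,
                              sodium_horizon = 8, sodium_interval = 6,
                              sodium_window = 60, retry_budget = 25L) {
  structure(list(lambda = as.integer(lambda), mu = as.integer(mu),
                 generations = as.integer(generations), Pf = Pf,
                 fit_tol = fit_tol,
                 constraints = if (is.null(constraints)) defaultConstraints()
                               else constraints,
                 sodium_horizon = sodium_horizon,
                 sodium_interval = sodium_interval,
                 sodium_window = sodium_window,
                 retry_budget = as.integer(retry_budget)),
            class = "patientGenOptions")
}

#' Default physiological constraints for patient fitting
#'
#' Box constraints imposed on the fitted equilibrium (and its settled
#' cardiac cycle, whose systolic/diastolic extremes appear among the
#' summary variables).
#'
#' @return a [constraintSet()].
#' @export
defaultConstraints <- function() {
  constraintSet(
    variables = c("EF", "LVEDP", "PAPsys", "PAPdia", "GFR", "P_glom",
                  "PRA", "AngII", "ALD", "RBF", "EDV", "ESV"),
    lower = c(50, 2, 8, 4, 55, 38, 5, 0.5, 80, 0.6, 70, 10),
    upper = c(80, 16, 32, 20, 150, 62, 120, 14, 350, 1.8, 170, 80)
  )
}

# Watson total-body-water and Nadler blood-volume anthropometrics (age
# fixed at 50 years for the TBW formula; the study population carries no
# age variable). ECF is taken as TBW/3.
anthropometricVolumes <- function(BW, BH, sex) {
  TBW <- if (sex == "male") {
    2.447 - 0.09156 * 50 + 0.1074 * BH + 0.3362 * BW
  } else {
    -2.097 + 0.1069 * BH + 0.2466 * BW
  }
  H_m <- BH / 100
  BV <- if (sex == "male") {
    0.3669 * H_m^3 + 0.03219 * BW + 0.6041
  } else {
    0.3561 * H_m^3 + 0.03308 * BW + 0.1833
  }
  list(TBW = TBW, ECF = TBW / 3, BV = BV)
}

# fitted parameter vector layout
.patientParNames <- c("HR0", "c0", "SVR0", "E_sa0", "phi_sodin", "fe0",
                      "V_ecf_ref", "bv_frac", "Es_scale", "MAP_ref",
                      "R0_scale", "ALD0_scale", "at1_gain")

patientParBounds <- function(draw, vols) {
  MAP_est <- draw$DBP + 0.5 * (draw$SBP - draw$DBP)
  bvf <- vols$BV / vols$ECF
  lower <- c(HR0 = 45, c0 = 0.7, SVR0 = 0.7, E_sa0 = 0.5,
             phi_sodin = 0.028, fe0 = 0.003,
             V_ecf_ref = 0.85 * vols$ECF, bv_frac = 0.9 * bvf,
             Es_scale = 0.75, MAP_ref = 0.85 * MAP_est,
             R0_scale = 0.6, ALD0_scale = 0.6, at1_gain = 0.7)
  upper <- c(HR0 = 110, c0 = 1.4, SVR0 = 2.4, E_sa0 = 1.5,
             phi_sodin = 0.209, fe0 = 0.02,
             V_ecf_ref = 1.15 * vols$ECF, bv_frac = 1.1 * bvf,
             Es_scale = 1.3, MAP_ref = 1.15 * MAP_est,
             R0_scale = 1.5, ALD0_scale = 1.5, at1_gain = 1.35)
  list(lower = lower, upper = upper, MAP_est = MAP_est)
}

# assemble a full parameter object from a fitted vector; the circulation's
# unstressed volumes scale with the anthropometric blood volume so that
# small subjects are not left with collapsed filling
buildPatientParams <- function(theta, cACE, vols) {
  names(theta) <- .patientParNames
  p <- defaultParameters(cACE = cACE)
  v0s <- vols$BV / 5.0
  for (nm in c("V0_lv", "V0_sa", "V0_sv", "V0_rv", "V0_pa", "V0_pv")) {
    p$cardiac[[nm]] <- p$cardiac[[nm]] * v0s
  }
  p$cardiac$HR0 <- theta[["HR0"]]
  p$cardiac$c0 <- theta[["c0"]]
  p$vascular$SVR0 <- theta[["SVR0"]]
  p$cardiac$E_sa0 <- theta[["E_sa0"]]
  p$cardiac$Es_scale <- theta[["Es_scale"]]
  p$sodium$phi_sodin <- theta[["phi_sodin"]]
  p$sodium$fe0 <- theta[["fe0"]]
  p$volume$V_ecf_ref <- theta[["V_ecf_ref"]]
  p$volume$bv_frac <- theta[["bv_frac"]]
  p$baro$MAP_ref <- theta[["MAP_ref"]]
  p$scales$R0_scale <- theta[["R0_scale"]]
  p$scales$ALD0_scale <- theta[["ALD0_scale"]]
  p$raas$at1_gain <- theta[["at1_gain"]]
  p
}

heuristicSeed <- function(draw, vols, bounds) {
  PP <- draw$SBP - draw$DBP
  seedv <- c(HR0 = draw$HR, c0 = 1,
             SVR0 = (bounds$MAP_est - 5) / (draw$SV * draw$HR / 60),
             E_sa0 = 0.9 * (PP / 52.8) * (70.3 / draw$SV),
             phi_sodin = 0.13, fe0 = 0.0097,
             V_ecf_ref = vols$ECF, bv_frac = vols$BV / vols$ECF,
             Es_scale = 1, MAP_ref = bounds$MAP_est,
             R0_scale = 1, ALD0_scale = 1, at1_gain = 1)
  pmin(pmax(seedv, bounds$lower), bounds$upper)
}

# Cheap Gauss-Seidel polish of the heuristic seed: a few multiplicative
# corrections of the most directly coupled parameters (intrinsic heart rate,
# vascular tone, arterial elasticity, volume set point, baroreflex set
# point) against a coarse equilibrium solve. Returns a small matrix of
# candidate seeds for the optimizer's first generation.
refineSeed <- function(seed0, draw, cACE, vols, bounds, cache_warm = NULL) {
  th <- seed0
  seeds <- matrix(th, nrow = 1)
  warm <- cache_warm
  gpn <- defaultParameters()$sodium$g_pn
  for (k in 1:6) {
    p <- buildPatientParams(th, cACE, vols)
    eq <- tryCatch(steadyState(p, precision = "coarse", warm = warm),
                   raasimError = function(e) NULL)
    if (is.null(eq)) break
    warm <- eq
    PPt <- draw$SBP - draw$DBP
    PPa <- eq$SBP - eq$DBP
    # where the mean sits between DBP and SBP in the achieved waveform
    xa <- (eq$MAP - eq$DBP) / PPa
    MAPt <- draw$DBP + xa * PPt
    dmp <- 0.7  # damped multiplicative corrections
    th[["HR0"]] <- th[["HR0"]] * (draw$HR / eq$HR)^dmp
    th[["MAP_ref"]] <- eq$MAP * (MAPt / eq$MAP)^0.3
    # equilibrium pressure is set by the renal function curve: shift it
    # through the excretion coefficient (fe ~ fe0 * MAP^g_pn)
    th[["fe0"]] <- th[["fe0"]] * (eq$MAP / MAPt)^(gpn * dmp)
    # vascular tone trades blood volume (hence filling and SV) at the
    # renally-set pressure
    th[["SVR0"]] <- th[["SVR0"]] * (eq$SV / draw$SV)^dmp
    th[["E_sa0"]] <- th[["E_sa0"]] * ((PPt / PPa) * (eq$SV / draw$SV))^dmp
    th[["V_ecf_ref"]] <- eq$V_ecf  # renin volume set point tracks the solution
    th[["c0"]] <- th[["c0"]] * (draw$SV / eq$SV)^0.2
    th <- pmin(pmax(th, bounds$lower), bounds$upper)
    seeds <- rbind(seeds, th)
  }
  seeds[rev(seq_len(nrow(seeds))), , drop = FALSE]
}

typedFailure <- function(reason, detail = NULL) {
  structure(list(reason = reason, detail = detail), class = "patientFailure")
}

#' Generate one virtual patient from a demographic draw
#'
#' Solves the constrained fitting problem: find a model parameterisation
#' whose equilibrium reproduces the draw's SBP, DBP, HR and SV (normalised
#' distance objective) while keeping every constrained variable inside its
#' physiological box (quadratic penalty), using the stochastic ranking
#' evolution strategy seeded with one heuristic candidate. Body weight,
#' height and sex bound total body water (hence the extracellular volume set
#' point) and total blood volume via standard anthropometric formulas. An
#' accepted patient has every target within `fit_tol`, zero penalty, and
#' passes the sodium-loading test.
#'
#' @param draw one-row data frame from [sampleDemographics()].
#' @param group `"L"` or `"H"` (sets cACE together with `genotype`).
#' @param genotype `"II"`, `"ID"` or `"DD"`.
#' @param constraints optional [constraintSet()] overriding the options'.
#' @param options a [patientGenOptions()].
#' @param seed integer seed for the optimizer.
#' @return a `virtualPatient` on success, otherwise a `patientFailure` with
#'   `reason` one of `"no-convergence"`, `"constraint-violation"`,
#'   `"sodium-test-failed"`, `"fit-tolerance"`.
#' @export
generatePatient <- function(draw, group, genotype, constraints = NULL,
                            options = patientGenOptions(), seed = 1) {
  draw <- as.list(draw)
  if (!passesCriteria(draw)) {
    stopTyped("invalidArgument", "draw does not satisfy the study criteria")
  }
  cACE <- assignGroupActivity(group, genotype)
  cons <- if (is.null(constraints)) options$constraints else constraints
  vols <- anthropometricVolumes(draw$BW, draw$BH, draw$sex)
  bounds <- patientParBounds(draw, vols)
  targets <- targetProfile(c(SBP = draw$SBP, DBP = draw$DBP, HR = draw$HR,
                             SV = draw$SV))

  # hormonal and myocardial scales are not pinned by the haemodynamic
  # targets: sample them per patient so subpopulations carry realistic
  # biomarker and ejection-fraction spread (the fit then works around them)
  set.seed(as.integer(seed %% .Machine$integer.max))
  seed0 <- heuristicSeed(draw, vols, bounds)
  seed0[["at1_gain"]] <- stats::runif(1, 0.75, 1.30)
  seed0[["R0_scale"]] <- stats::runif(1, 0.92, 1.08)
  seed0[["ALD0_scale"]] <- stats::runif(1, 0.85, 1.18)
  seed0[["Es_scale"]] <- stats::runif(1, 0.88, 1.18)
  seed0 <- pmin(pmax(seed0, bounds$lower), bounds$upper)

  cache <- new.env(parent = emptyenv())
  cache$warm <- NULL
  evalTheta <- function(theta) {
    key <- paste(signif(theta, 12), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    p <- buildPatientParams(theta, cACE, vols)
    res <- tryCatch({
      eq <- steadyState(p, precision = "coarse", warm = cache$warm)
      cache$warm <- eq
      X <- unlist(eq[c("SBP", "DBP", "HR", "SV")])
      row <- vapply(cons$variable, function(v) as.numeric(eq[[v]]), 0)
      list(obj = distanceObjective(X, targets),
           pen = penaltyValue(stats::setNames(row, cons$variable), cons))
    }, raasimError = function(e) list(obj = 1e6, pen = 1e6))
    cache[[key]] <- res
    res
  }

  seeds <- refineSeed(seed0, draw, cACE, vols, bounds)
  opt <- sresOptions(lambda = options$lambda, mu = options$mu,
                     generations = options$generations, Pf = options$Pf,
                     seed = seed, initial = seeds, step_frac = 0.04)
  fit <- sresOptimize(function(th) evalTheta(th)$obj,
                      function(th) evalTheta(th)$pen,
                      bounds$lower, bounds$upper, opt)

  p <- buildPatientParams(fit$par, cACE, vols)
  eq <- tryCatch(steadyState(p, warm = cache$warm),
                 raasimError = function(e) e)
  if (inherits(eq, "raasimError")) {
    return(typedFailure("no-convergence", conditionMessage(eq)))
  }
  row <- stats::setNames(vapply(cons$variable,
                                function(v) as.numeric(eq[[v]]), 0),
                         cons$variable)
  pen <- penaltyValue(row, cons)
  if (pen > 0) {
    return(typedFailure("constraint-violation", pen))
  }
  X <- unlist(eq[c("SBP", "DBP", "HR", "SV")])
  relerr <- abs(X - targets$desired) / targets$desired
  if (any(relerr > options$fit_tol)) {
    return(typedFailure("fit-tolerance", relerr))
  }
  pat <- virtualPatient(p, eq, demographics = draw, group = group,
                        genotype = genotype,
                        objective = distanceObjective(X, targets),
                        penalty = pen, seed = seed,
                        diagnostics = list(evaluations = fit$evaluations,
                                           fit_errors = relerr))
  na <- sodiumLoadTest(pat, horizon = options$sodium_horizon,
                       interval = options$sodium_interval,
                       window = options$sodium_window)
  if (!isTRUE(na$pass)) {
    return(typedFailure("sodium-test-failed", na$delta_SBP))
  }
  pat$diagnostics$sodium <- na[c("pass", "delta_SBP")]
  pat
}
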