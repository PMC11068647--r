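# Synthetic study population: demographic sampling, inclusion/exclusion
# screening and the genotype -> ACE-activity table.

#' Body height from weight and body-mass index
#'
#' By the BMI definition `BMI = BW / (BH/100)^2`, height in centimetres is
#' `BH = 100 * sqrt(BW / BMI)`.
#'
#' @param BW body weight (kg), positive.
#' @param BMI body-mass index (kg/m^2), positive.
#' @return body height (cm).
#' @examples
#' heightFromWeightBmi(80, 29) # 166.1 cm
#' @export
heightFromWeightBmi <- function(BW, BMI) {
  assertPositive(c(BW, BMI), "BW and BMI")
  100 * sqrt(BW / BMI)
}

#' Inclusion/exclusion screening of a demographic draw
#'
#' Inclusion: essential hypertension (SBP >= 140 mmHg and/or DBP >= 90 mmHg,
#' with SBP > 130 mmHg and DBP > 80 mmHg), BMI > 22 kg/m^2 and height
#' 160-180 cm. Exclusion: severe hypertension (SBP > 179.5 mmHg or
#' DBP > 109.5 mmHg), abnormal heart rate (HR < 60 or HR > 90 beats/min)
#' and severe obesity (BMI > 36 kg/m^2).
#'
#' @param draw a one-row data frame or named list with SBP, DBP, HR, BMI and
#'   BH (BH is derived from BW and BMI when absent).
#' @return `TRUE` if the draw enters the study population.
#' @export
passesCriteria <- function(draw) {
  d <- as.list(draw)
  if (is.null(d$BH)) d$BH <- heightFromWeightBmi(d$BW, d$BMI)
  inclusion <- (d$SBP >= 140 || d$DBP >= 90) && d$SBP > 130 && d$DBP > 80 &&
    d$BMI > 22 && d$BH >= 160 && d$BH <= 180
  exclusion <- d$SBP > 179.5 || d$DBP > 109.5 || d$HR < 60 || d$HR > 90 ||
    d$BMI > 36
  isTRUE(inclusion && !exclusion)
}

#' Sample demographic target profiles for hypertensive virtual patients
#'
#' Draws SBP, DBP, HR, SV, BW and BMI from independent normal distributions
#' with means and standard deviations (160, 10) mmHg, (100, 10) mmHg,
#' (75, 10) beats/min, (70, 10) mL, (80, 20) kg and (29, 5) kg/m^2; sex is
#' selected with probability 0.5; height follows from BW and BMI. Draws are
#' rejected until the inclusion/exclusion screen passes, so the accepted
#' distribution is the stated normal truncated by the screening criteria.
#'
#' @param n number of accepted draws to return.
#' @param seed integer seed (draws are reproducible).
#' @return data frame with columns SBP, DBP, HR, SV, BW, BMI, BH, sex, and
#'   `attempts` (total raw draws consumed) as an attribute.
#' @export
sampleDemographics <- function(n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n)
  attempts <- 0L
  for (i in seq_len(n)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > 1e5 * max(n, 1)) {
        stopTyped("generationError", "demographic rejection loop stalled")
      }
      d <- list(SBP = stats::rnorm(1, 160, 10), DBP = stats::rnorm(1, 100, 10),
                HR = stats::rnorm(1, 75, 10), SV = stats::rnorm(1, 70, 10),
                BW = stats::rnorm(1, 80, 20), BMI = stats::rnorm(1, 29, 5))
      if (d$BW <= 0 || d$BMI <= 0) next
      d$BH <- heightFromWeightBmi(d$BW, d$BMI)
      d$sex <- if (stats::runif(1) < 0.5) "male" else "female"
      if (passesCriteria(d)) break
    }
    out[[i]] <- d
  }
  df <- do.call(rbind, lapply(out, function(d) {
    data.frame(SBP = d$SBP, DBP = d$DBP, HR = d$HR, SV = d$SV, BW = d$BW,
               BMI = d$BMI, BH = d$BH, sex = d$sex, stringsAsFactors = FALSE)
  }))
  attr(df, "attempts") <- attempts
  df
}

.aceActivityTable <- matrix(
  c(7.0, 8.9, 10.8,
    42.3, 54.1, 65.9),
  nrow = 2, byrow = TRUE,
  dimnames = list(c("L", "H"), c("II", "ID", "DD"))
)

#' ACE activity of a (group, genotype) combination
#'
#' Fixed table derived from the group means (8.9 and 54.1 1/h) and the
#' 28%/56% activity increase of the ID and DD genotypes over II:
#' L: 7.0, 8.9, 10.8; H: 42.3, 54.1, 65.9 (1/h).
#'
#' @param group `"L"` (low ACE activity) or `"H"` (high).
#' @param genotype `"II"`, `"ID"` or `"DD"`.
#' @return ACE activity cACE (1/h).
#' @examples
#' assignGroupActivity("H", "II") # 42.3
#' @export
assignGroupActivity <- function(group, genotype) {
  if (!group %in% rownames(.aceActivityTable) ||
      !genotype %in% colnames(.aceActivityTable)) {
    stopTyped("invalidArgument", "unknown group or genotype")
  }
  .aceActivityTable[group, genotype]
}

#' Generate a genotype subpopulation of virtual patients
#'
#' Runs the full generation loop: sample demographics (rejection-screened),
#' bound the volume parameters from body weight, height and sex, fit the
#' model to the draw's haemodynamic targets with the stochastic ranking
#' evolution strategy, and accept the patient only if the fit is within
#' tolerance with zero constraint penalty and the sodium-loading test
#' passes. Per-patient seeds are derived from the population seed by a
#' counter scheme, so the population record is a pure function of
#' `(n, group, genotype, seed, options)`.
#'
#' @param n number of accepted patients.
#' @param group `"L"` or `"H"`.
#' @param genotype `"II"`, `"ID"` or `"DD"`.
#' @param seed population seed (small integer).
#' @param options optimizer/acceptance options from [patientGenOptions()].
#' @param verbose print per-patient progress.
#' @return a `population` object: list with `patients` (list of
#'   `virtualPatient`), `label`, `seed`, and attrition counts.
#' @export
generatePopulation <- function(n, group, genotype, seed = 1,
                               options = patientGenOptions(),
                               verbose = FALSE) {
  if (n < 1) stopTyped("invalidArgument", "n must be at least 1")
  cACE <- assignGroupActivity(group, genotype)
  patients <- vector("list", n)
  accepted <- 0L
  attempt <- 0L
  failures <- c(`no-convergence` = 0L, `constraint-violation` = 0L,
                `sodium-test-failed` = 0L, `fit-tolerance` = 0L)
  base_seed <- (as.integer(seed) %% 1000000L)
  while (accepted < n) {
    attempt <- attempt + 1L
    if (attempt > options$retry_budget * n) {
      stopTyped("generationError",
                sprintf("acceptance rate too low: %d/%d after %d attempts (%s)",
                        accepted, n, attempt,
                        paste(names(failures), failures, sep = "=",
                              collapse = ", ")))
    }
    patient_seed <- base_seed * 1000L + attempt
    draw <- sampleDemographics(1, seed = patient_seed)
    res <- generatePatient(draw, group, genotype, options = options,
                           seed = patient_seed)
    if (inherits(res, "virtualPatient")) {
      accepted <- accepted + 1L
      patients[[accepted]] <- res
      if (verbose) {
        message(sprintf("  [%s%s] patient %d/%d (attempt %d): obj %.3g",
                        group, genotype, accepted, n, attempt, res$objective))
      }
    } else {
      failures[res$reason] <- failures[res$reason] + 1L
      if (verbose) message(sprintf("  [%s%s] attempt %d rejected: %s",
                                   group, genotype, attempt, res$reason))
    }
  }
  structure(list(patients = patients, label = paste0(group, genotype),
                 group = group, genotype = genotype, cACE = cACE,
                 seed = as.integer(seed), attempts = attempt,
                 failures = failures),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("Virtual subpopulation %s (cACE %.1f 1/h): %d patients, %d attempts\n",
              x$label, x$cACE, length(x$patients), x$attempts))
  if (any(x$failures > 0)) {
    cat("  rejections:", paste(names(x$failures)[x$failures > 0],
                               x$failures[x$failures > 0], sep = "=",
                               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract a per-patient summary table from a population
#'
#' @param pop a `population`.
#' @param variables equilibrium variables to extract (default: all).
#' @return data frame, one row per patient: demographics, genotype, seed and
#'   the requested baseline equilibrium variables.
#' @export
populationTable <- function(pop, variables = NULL) {
  rows <- lapply(pop$patients, function(p) {
    eq <- p$baseline
    meta <- data.frame(group = pop$group, genotype = pop$genotype,
                       cACE = p$cACE, seed = p$seed,
                       BW = p$demographics$BW, BMI = p$demographics$BMI,
                       BH = p$demographics$BH, sex = p$demographics$sex,
                       stringsAsFactors = FALSE)
    vars <- if (is.null(variables)) {
      names(eq)[vapply(eq, function(v) is.numeric(v) && length(v) == 1, TRUE)]
    } else variables
    vars <- setdiff(vars, names(meta))
    vals <- vapply(vars, function(v) {
      x <- eq[[v]]
      if (is.null(x)) NA_real_ else as.numeric(x)
    }, 0)
    cbind(meta, as.data.frame(as.list(vals)))
  })
  do.call(rbind, rows)
}
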