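# Study analyses: ACE-activity sweep, population summaries, KS treatment
# comparisons and baseline-biomarker/response correlations.

#' Equilibrium blood pressure across an ACE-activity grid
#'
#' Recomputes the patient's equilibrium at each grid value of cACE with all
#' other parameters fixed, giving the blood-pressure-versus-ACE-activity
#' curve whose saturating shape underlies the genotype hypotheses.
#'
#' @param patient a `virtualPatient` (or `raasimParams`).
#' @param grid strictly increasing cACE values (1/h), within 0.5-200.
#' @return a `sweepCurve` data frame: `cACE`, `SBP`, `DBP`, plus equilibrium
#'   `MAP`, `AngII` and `converged`; attribute `diffs` holds the first
#'   differences of SBP and `plateau` the final SBP value.
#' @export
aceSweep <- function(patient, grid = c(0.5, 1, 2, 4, 6, 8.9, 12, 18, 27,
                                       42.3, 54.1, 65.9, 90, 120, 160, 200)) {
  params <- if (inherits(patient, "virtualPatient")) patient$params else patient
  if (is.unsorted(grid, strictly = TRUE) || any(grid < 0.5) ||
      any(grid > 200)) {
    stopTyped("invalidArgument", "grid must be strictly increasing in [0.5, 200]")
  }
  warm <- NULL
  rows <- lapply(grid, function(g) {
    p <- params
    p$rates$cACE <- g
    eq <- tryCatch(steadyState(p, warm = warm), raasimError = function(e) NULL)
    if (is.null(eq)) {
      return(data.frame(cACE = g, SBP = NA_real_, DBP = NA_real_,
                        MAP = NA_real_, AngII = NA_real_, converged = FALSE))
    }
    warm <<- eq
    data.frame(cACE = g, SBP = eq$SBP, DBP = eq$DBP, MAP = eq$MAP,
               AngII = eq$AngII, converged = TRUE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweepCurve", "data.frame")
  attr(out, "diffs") <- diff(out$SBP)
  attr(out, "plateau") <- out$SBP[nrow(out)]
  out
}

#' @describeIn aceSweep plot the pressure/activity curves (solid: SBP,
#'   dashed: DBP).
#' @param x a `sweepCurve`.
#' @param ... passed to [plot()].
#' @export
plot.sweepCurve <- function(x, ...) {
  graphics::plot(x$cACE, x$SBP, type = "l", lwd = 2, col = "steelblue",
                 xlab = expression(c[ACE] ~ (h^-1)),
                 ylab = "Pressure (mmHg)",
                 ylim = range(c(x$SBP, x$DBP), na.rm = TRUE), ...)
  graphics::lines(x$cACE, x$DBP, lwd = 2, lty = 2, col = "steelblue")
  graphics::legend("bottomright", c("SBP", "DBP"), lty = c(1, 2), lwd = 2,
                   col = "steelblue", bty = "n")
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' The statistic is `D = sup |F1 - F2|` over the pooled sample. P-values are
#' exact (full enumeration over label assignments, via the Smirnov
#' distribution) when `min(n, m) <= exact_max`, asymptotic otherwise.
#'
#' @param x,y numeric samples (non-empty).
#' @param variable optional variable label carried into the result.
#' @param exact_max largest `min(n, m)` for which the exact null
#'   distribution is used.
#' @return a `ksComparison` list: `variable`, `D`, `p`, `n`, `m`, `exact`,
#'   and `marker`, the significance marker at the study's reporting
#'   thresholds (`"***" p < 1e-5`, `"**" p < 1e-4`, `"*" p < 0.001`,
#'   `"." p < 0.05`).
#' @export
ksTwoSample <- function(x, y, variable = NA_character_, exact_max = 10) {
  if (!length(x) || !length(y)) {
    stopTyped("invalidArgument", "samples must be non-empty")
  }
  exact <- min(length(x), length(y)) <= exact_max
  kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  p <- unname(kt$p.value)
  marker <- if (p < 1e-5) "***" else if (p < 1e-4) "**" else
    if (p < 1e-3) "*" else if (p < 0.05) "." else ""
  structure(list(variable = variable, D = unname(kt$statistic), p = p,
                 n = length(x), m = length(y), exact = exact,
                 marker = marker),
            class = "ksComparison")
}

#' @export
print.ksComparison <- function(x, ...) {
  cat(sprintf("KS two-sample%s: D = %.4f, p = %.4g (n=%d, m=%d, %s)%s\n",
              if (is.na(x$variable)) "" else paste0(" [", x$variable, "]"),
              x$D, x$p, x$n, x$m,
              if (x$exact) "exact" else "asymptotic",
              if (nzchar(x$marker)) paste0(" ", x$marker) else ""))
  invisible(x)
}

#' Mean/SD summary of a virtual population
#'
#' @param pop a `population` (or a plain data frame of per-patient values).
#' @param variables equilibrium variables to summarise; defaults to the
#'   reported roster (haemodynamics, ventricular, renal, intraglomerular and
#'   RAAS variables).
#' @return a `summaryTable` data frame: `variable`, `mean`, `sd`, `n`.
#' @export
summarizePopulation <- function(pop, variables = NULL) {
  if (inherits(pop, "population")) {
    if (!length(pop$patients)) {
      stopTyped("invalidArgument", "population is empty")
    }
    tab <- populationTable(pop, variables)
    num <- setdiff(names(tab)[vapply(tab, is.numeric, TRUE)], "seed")
    if (!is.null(variables)) num <- intersect(variables, num)
    tab <- tab[num]
  } else {
    tab <- as.data.frame(pop)
    if (!nrow(tab)) stopTyped("invalidArgument", "population is empty")
    tab <- tab[vapply(tab, is.numeric, TRUE)]
    if (!is.null(variables)) tab <- tab[intersect(variables, names(tab))]
  }
  out <- data.frame(
    variable = names(tab),
    mean = vapply(tab, mean, 0),
    sd = vapply(tab, stats::sd, 0),
    n = nrow(tab),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("summaryTable", "data.frame")
  out
}

# default variable roster mirroring the reported baseline table
.reportRoster <- c("BMI", "BW", "SBP", "DBP", "HR", "E_sa", "SVR", "PAPdia", "PAPsys",
                   "PVR", "SV", "EF", "LVEDP", "LVPSP", "EDV", "ESV",
                   "RVEDP", "RVPSP", "RVEDV", "RVESV", "GFR", "RBF", "RVR",
                   "d_aff", "d_eff", "R_aff", "R_eff", "P_glom", "Na_conc",
                   "PRA", "AngI", "AngII", "ALD")

#' Roster of reported equilibrium variables
#' @return character vector of the variables summarised in population tables.
#' @export
reportRoster <- function() .reportRoster

#' Treatment-change table with KS comparisons
#'
#' Simulates each regimen on every patient of one or more subpopulations and
#' tabulates per-regimen mean +/- SD of the endpoint-minus-baseline changes,
#' with Kolmogorov-Smirnov tests of endpoint versus baseline within each
#' subpopulation; when two or more populations are given, the corresponding
#' deltas are also compared across subpopulations (first population as
#' reference). P-values are reported raw, with fixed significance markers,
#' as in the study's reporting convention.
#'
#' @param pops a `population` or list of them.
#' @param regimens list of regimen character vectors (e.g.
#'   `list(placebo = character(), E20 = "enalapril 20")`).
#' @param variables variables to tabulate (default SBP and DBP).
#' @param catalogue drug catalogue.
#' @param ... passed to [simulateTreatment()].
#' @return a `treatmentChangeTable` data frame with one row per
#'   (population, regimen, variable): mean/sd of delta, KS D and p for
#'   endpoint-vs-baseline, and (if applicable) KS D and p of delta versus
#'   the reference population's delta. The per-patient deltas are kept in
#'   attribute `deltas`.
#' @export
treatmentChangeTable <- function(pops, regimens, variables = c("SBP", "DBP"),
                                 catalogue = drugCatalogue(), ...) {
  if (inherits(pops, "population")) pops <- list(pops)
  if (is.null(names(regimens))) {
    names(regimens) <- vapply(regimens, function(r) {
      if (!length(r)) "placebo" else paste(r, collapse = "+")
    }, "")
  }
  rows <- list()
  deltas <- list()
  for (ri in names(regimens)) {
    for (pi in seq_along(pops)) {
      pop <- pops[[pi]]
      outs <- lapply(pop$patients, simulateTreatment,
                     regimen = regimens[[ri]], catalogue = catalogue, ...)
      for (v in variables) {
        dl <- vapply(outs, function(o) o$delta[[v]], 0)
        b <- vapply(outs, function(o) o$baseline[[v]], 0)
        e <- vapply(outs, function(o) o$endpoint[[v]], 0)
        ksEB <- ksTwoSample(e, b, variable = v)
        key <- paste(pop$label, ri, v, sep = ".")
        deltas[[key]] <- dl
        row <- data.frame(population = pop$label, regimen = ri,
                          variable = v, mean_delta = mean(dl),
                          sd_delta = stats::sd(dl), n = length(dl),
                          D_endpoint = ksEB$D, p_endpoint = ksEB$p,
                          marker = ksEB$marker,
                          D_vs_ref = NA_real_, p_vs_ref = NA_real_,
                          stringsAsFactors = FALSE)
        if (pi > 1) {
          refKey <- paste(pops[[1]]$label, ri, v, sep = ".")
          ksAB <- ksTwoSample(dl, deltas[[refKey]], variable = v)
          row$D_vs_ref <- ksAB$D
          row$p_vs_ref <- ksAB$p
        }
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "deltas") <- deltas
  class(out) <- c("treatmentChangeTable", "data.frame")
  out
}

#' Correlation between baseline RAAS biomarkers and DBP reduction
#'
#' For every patient of a population the regimen is simulated and the DBP
#' reduction (baseline minus endpoint, so larger is a stronger response) is
#' correlated with the patient's baseline biomarker levels.
#'
#' @param pop a `population`.
#' @param regimen regimen character vector.
#' @param biomarkers baseline variables to correlate (default PRA, Ang I,
#'   Ang II).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param outcomes optional precomputed list of `treatmentOutcome`s aligned
#'   with `pop$patients` (skips re-simulation).
#' @param ... passed to [simulateTreatment()].
#' @return data frame: `biomarker`, `r` (NA with `undefined = TRUE` when a
#'   variance is zero), `n`.
#' @export
baselineResponseCorrelation <- function(pop, regimen,
                                        biomarkers = c("PRA", "AngI", "AngII"),
                                        method = c("pearson", "spearman"),
                                        outcomes = NULL, ...) {
  method <- match.arg(method)
  if (is.null(outcomes)) {
    outcomes <- lapply(pop$patients, simulateTreatment, regimen = regimen,
                       ...)
  }
  reduction <- vapply(outcomes, function(o) -o$delta[["DBP"]], 0)
  rows <- lapply(biomarkers, function(bm) {
    x <- vapply(pop$patients, function(p) as.numeric(p$baseline[[bm]]), 0)
    if (stats::sd(x) == 0 || stats::sd(reduction) == 0) {
      data.frame(biomarker = bm, r = NA_real_, n = length(x),
                 undefined = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(biomarker = bm,
                 r = stats::cor(x, reduction, method = method),
                 n = length(x), undefined = FALSE, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
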