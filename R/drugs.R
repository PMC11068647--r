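#' Pharmacodynamic influence factor
#'
#' A drug multiplies its target variable by `F = 1 + E*d` (stimulation) or
#' `F = 1 - E*d` (inhibition), where `E` in `[0, 1)` is the effect magnitude
#' and `d` in `{0, 1}` indicates whether the drug is being given.
#'
#' @param E effect magnitude, `0 <= E < 1`.
#' @param d drug indicator, 0 or 1.
#' @param sign `"stimulation"` or `"inhibition"`.
#' @return the multiplicative factor.
#' @examples
#' influenceFactor(0.25, 1, "inhibition") # 0.75
#' influenceFactor(0.4, 0, "stimulation") # 1
#' @export
influenceFactor <- function(E, d, sign = c("inhibition", "stimulation")) {
  sign <- match.arg(sign)
  if (!is.numeric(E) || any(!is.finite(E)) || any(E < 0) || any(E >= 1)) {
    stopTyped("invalidArgument", "effect magnitude must lie in [0, 1)")
  }
  if (!all(d %in% c(0, 1))) {
    stopTyped("invalidArgument", "drug indicator must be 0 or 1")
  }
  if (sign == "stimulation") 1 + E * d else 1 - E * d
}

#' The antihypertensive drug catalogue
#'
#' Six drugs at one (label) dose each: the direct renin inhibitor aliskiren
#' 300 mg, the ACE inhibitor enalapril 20 mg, the angiotensin II receptor
#' blocker losartan 100 mg, the beta-blocker bisoprolol 5 mg, the calcium
#' channel blocker amlodipine 5 mg and the thiazide diuretic
#' hydrochlorothiazide 12.5 mg. Each drug carries one or more target effects
#' (registry name, sign, magnitude). Doses are identifiers: no
#' pharmacokinetics is modelled. Effect magnitudes were calibrated once so
#' that each monotherapy lowers systolic pressure by roughly 5-15 mmHg on the
#' default high-ACE patient; they live in the editable YAML file
#' `system.file("extdata", "drug_catalogue.yaml", package = "raasim")`.
#'
#' @param file optional path to an alternative catalogue YAML file.
#' @return a `drugCatalogue`: named list of drugs, each with `dose` and a
#'   data.frame `effects` (`target`, `sign`, `E`).
#' @export
drugCatalogue <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "drug_catalogue.yaml", package = "raasim")
  }
  raw <- yaml::read_yaml(file)
  out <- lapply(raw, function(d) {
    eff <- do.call(rbind, lapply(d$effects, function(e) {
      data.frame(target = e$target, sign = e$sign, E = as.numeric(e$E),
                 stringsAsFactors = FALSE)
    }))
    bad <- setdiff(eff$target, effectTargets())
    if (length(bad)) {
      stopTyped("configurationError",
                paste("catalogue targets not in effect registry:",
                      paste(bad, collapse = ", ")))
    }
    list(dose = d$dose, effects = eff)
  })
  structure(out, class = "drugCatalogue")
}

catalogueKey <- function(name, dose) {
  paste(name, format(dose, trim = TRUE, drop0trailing = TRUE))
}

#' Compose a treatment regimen from drug names with doses
#'
#' @param names_with_doses character vector like
#'   `c("enalapril 20", "amlodipine 5")`; order-insensitive. An empty vector
#'   is the placebo regimen. Shorthand strings such as `"E20+Aml5+B5"` are
#'   not parsed; use full names.
#' @param catalogue a [drugCatalogue()].
#' @return a `regimen`: named 0/1 indicator vector over the catalogue drugs.
#' @examples
#' \dontrun{
#' buildRegimen(c("aliskiren 300", "amlodipine 5", "bisoprolol 5"))
#' }
#' @export
buildRegimen <- function(names_with_doses = character(),
                         catalogue = drugCatalogue()) {
  keys <- vapply(names(catalogue), function(nm) {
    catalogueKey(nm, catalogue[[nm]]$dose)
  }, "")
  ind <- stats::setNames(rep(0L, length(catalogue)), names(catalogue))
  for (entry in names_with_doses) {
    entry <- trimws(entry)
    hit <- which(keys == entry)
    if (!length(hit)) {
      stopTyped("catalogueError",
                sprintf("'%s' is not in the drug catalogue (%s)", entry,
                        paste(keys, collapse = "; ")))
    }
    ind[hit] <- 1L
  }
  structure(ind, class = "regimen")
}

#' Effect multipliers of a regimen
#'
#' Evaluates the influence factor of every effect of every active drug and
#' composes factors hitting the same target multiplicatively.
#'
#' @param regimen a [buildRegimen()] result (or a character vector passed
#'   through it).
#' @param catalogue a [drugCatalogue()].
#' @return an `effectMultipliers`: named factor vector over
#'   [effectTargets()], all 1 for the placebo regimen.
#' @export
applyRegimen <- function(regimen, catalogue = drugCatalogue()) {
  if (is.character(regimen)) regimen <- buildRegimen(regimen, catalogue)
  fac <- neutralEffects()
  for (nm in names(catalogue)) {
    d <- if (nm %in% names(regimen)) regimen[[nm]] else 0L
    if (d == 0) next
    eff <- catalogue[[nm]]$effects
    for (k in seq_len(nrow(eff))) {
      fac[[eff$target[k]]] <- fac[[eff$target[k]]] *
        influenceFactor(eff$E[k], 1, eff$sign[k])
    }
  }
  structure(fac, class = "effectMultipliers")
}

#' @export
print.drugCatalogue <- function(x, ...) {
  cat("Drug catalogue:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", catalogueKey(nm, x[[nm]]$dose),
                paste(sprintf("%s %s %.3g", x[[nm]]$effects$sign,
                              x[[nm]]$effects$target, x[[nm]]$effects$E),
                      collapse = "; ")))
  }
  invisible(x)
}
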