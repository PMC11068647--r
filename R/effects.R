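# Registry of model quantities a drug can act on. Each entry is a named
# multiplicative factor applied inside the model equations; 1 means no drug
# action on that target.

.effectTargets <- c(
  "ace_activity",        # ACE catalytic rate (enalapril)
  "renin_activity",      # catalytic activity of circulating renin (aliskiren)
  "renin_secretion",     # renin secretion drive (bisoprolol)
  "at1_receptor",        # AT1 receptor signal transduction (losartan)
  "heart_rate",          # chronotropic command (bisoprolol)
  "contractility",       # inotropic state (bisoprolol)
  "arterial_elastance",  # systemic arterial stiffness (bisoprolol)
  "vascular_tone",       # systemic resistance vessel tone (amlodipine)
  "afferent_tone",       # afferent arteriolar tone (amlodipine)
  "sodium_reabsorption"  # tubular sodium reabsorption (hydrochlorothiazide)
)

#' Names of registered drug-effect targets
#'
#' @return character vector of model quantities that pharmacodynamic
#'   influence functions may multiply.
#' @export
effectTargets <- function() .effectTargets

#' Neutral effect multipliers
#'
#' @return named numeric vector of 1s over [effectTargets()], i.e. no drug.
#' @export
neutralEffects <- function() {
  stats::setNames(rep(1, length(.effectTargets)), .effectTargets)
}

asEffects <- function(effects) {
  if (is.null(effects)) return(neutralEffects())
  if (inherits(effects, "effectMultipliers")) effects <- unclass(effects)
  out <- neutralEffects()
  if (length(effects)) {
    unknown <- setdiff(names(effects), .effectTargets)
    if (length(unknown)) {
      stopTyped("configurationError",
                paste("unknown effect target(s):", paste(unknown, collapse = ", ")))
    }
    out[names(effects)] <- as.numeric(effects)
  }
  out
}
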