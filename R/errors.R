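# Typed conditions used across the package. Tests and callers can catch a
# failure class rather than matching message text.

stopTyped <- function(class, msg, ...) {
  extra <- list(...)
  cond <- structure(
    class = c(class, "raasimError", "error", "condition"),
    c(list(message = msg, call = sys.call(-1)), extra)
  )
  stop(cond)
}

assertFiniteNonNegative <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stopTyped("invalidArgument", sprintf("%s must be finite and non-negative", what))
  }
  invisible(x)
}

assertPositive <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stopTyped("invalidArgument", sprintf("%s must be finite and positive", what))
  }
  invisible(x)
}
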