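#' Target profile for virtual-patient fitting
#'
#' Desired equilibrium values with the weighting of the normalised-distance
#' objective: each target's weight is its desired value, and the objective
#' scales every squared residual by `w_min / w_i`.
#'
#' @param targets named numeric vector of desired values (all positive),
#'   typically SBP, DBP, HR and SV.
#' @return a `targetProfile`.
#' @export
targetProfile <- function(targets) {
  if (!length(targets) || is.null(names(targets)) || any(targets <= 0) ||
      any(!is.finite(targets))) {
    stopTyped("invalidArgument", "targets must be named, finite and positive")
  }
  structure(list(desired = targets, weights = targets,
                 w_min = min(targets)), class = "targetProfile")
}

#' Normalised distance objective between simulated and desired values
#'
#' `sum_i (w_min / w_i) * (X_i - Xdes_i)^2` with `w_i = Xdes_i`.
#'
#' @param X named (or aligned) numeric vector of simulated values.
#' @param targets a [targetProfile()] or a named vector passed through it.
#' @return non-negative objective value.
#' @examples
#' distanceObjective(c(SBP = 110, DBP = 50), targetProfile(c(SBP = 100, DBP = 50)))
#' @export
distanceObjective <- function(X, targets) {
  if (!inherits(targets, "targetProfile")) targets <- targetProfile(targets)
  des <- targets$desired
  if (!is.null(names(X))) {
    miss <- setdiff(names(des), names(X))
    if (length(miss)) {
      stopTyped("invalidArgument",
                paste("simulated values missing targets:",
                      paste(miss, collapse = ", ")))
    }
    X <- X[names(des)]
  } else if (length(X) != length(des)) {
    stopTyped("invalidArgument", "X and targets are not aligned")
  }
  sum((targets$w_min / targets$weights) * (X - des)^2)
}

#' Box constraints on trajectory variables
#'
#' @param variables character vector of constrained variable names.
#' @param lower,upper numeric bounds, `lower <= upper` elementwise.
#' @return a `constraintSet` data frame.
#' @export
constraintSet <- function(variables, lower, upper) {
  if (length(variables) != length(lower) || length(lower) != length(upper)) {
    stopTyped("invalidArgument", "constraint vectors must be the same length")
  }
  if (any(lower > upper)) {
    stopTyped("invalidArgument", "constraint lower bounds exceed upper bounds")
  }
  structure(data.frame(variable = variables, lower = lower, upper = upper,
                       stringsAsFactors = FALSE), class = c("constraintSet",
                                                            "data.frame"))
}

#' Quadratic penalty of constraint violations over a sampled trajectory
#'
#' `sum_t sum_j [max(0, lo_j - Y_j(t))^2 + max(0, Y_j(t) - hi_j)^2]`.
#'
#' @param trajectory numeric matrix (rows: time samples) whose columns
#'   include every constrained variable, or a named vector for a single
#'   sample.
#' @param constraints a [constraintSet()].
#' @return non-negative penalty value.
#' @export
penaltyValue <- function(trajectory, constraints) {
  if (is.null(dim(trajectory))) {
    trajectory <- matrix(trajectory, nrow = 1,
                         dimnames = list(NULL, names(trajectory)))
  }
  miss <- setdiff(constraints$variable, colnames(trajectory))
  if (length(miss)) {
    stopTyped("invalidArgument",
              paste("trajectory lacks constrained variables:",
                    paste(miss, collapse = ", ")))
  }
  total <- 0
  for (j in seq_len(nrow(constraints))) {
    y <- trajectory[, constraints$variable[j]]
    total <- total + sum(pmax(0, constraints$lower[j] - y)^2) +
      sum(pmax(0, y - constraints$upper[j])^2)
  }
  total
}

#' Options of the stochastic ranking evolution strategy
#'
#' Defaults follow common practice for this optimizer family
#' (`lambda = 200` offspring, `mu = 30` parents, `Pf = 0.45`,
#' 200 generations); the virtual-patient generator passes a smaller
#' desk-scale budget.
#'
#' @param lambda offspring population size.
#' @param mu parent count (`mu < lambda`).
#' @param generations number of generations.
#' @param Pf stochastic-ranking probability of comparing by objective when
#'   at least one candidate is infeasible (`0 < Pf < 0.5`).
#' @param seed integer seed for reproducibility.
#' @param initial optional numeric matrix (rows = candidate vectors) seeded
#'   into the first generation, e.g. a heuristic initial guess.
#' @param step_frac initial step size as a fraction of each box width
#'   (default `1/sqrt(d)`); smaller values suit polishing a good seed.
#' @return an `sresOptions` list.
#' @export
sresOptions <- function(lambda = 200L, mu = 30L, generations = 200L,
                        Pf = 0.45, seed = 1L, initial = NULL,
                        step_frac = NULL) {
  if (!(Pf > 0 && Pf < 0.5)) {
    stopTyped("invalidArgument", "Pf must lie in (0, 0.5)")
  }
  if (!(mu < lambda)) {
    stopTyped("invalidArgument", "mu must be smaller than lambda")
  }
  structure(list(lambda = as.integer(lambda), mu = as.integer(mu),
                 generations = as.integer(generations), Pf = Pf,
                 seed = as.integer(seed), initial = initial,
                 step_frac = step_frac),
            class = "sresOptions")
}

# stochastic ranking: adjacent-pair bubble sort over lambda candidates;
# a pair is compared by objective with probability Pf, or always when both
# are feasible (penalty 0); otherwise by penalty. N sweeps with early exit.
stochasticRank <- function(obj, pen, Pf) {
  n <- length(obj)
  idx <- seq_len(n)
  for (sweep in seq_len(n)) {
    swapped <- FALSE
    u <- stats::runif(n - 1)
    for (k in seq_len(n - 1)) {
      i <- idx[k]; j <- idx[k + 1]
      byObj <- (pen[i] == 0 && pen[j] == 0) || u[k] < Pf
      swap <- if (byObj) obj[i] > obj[j] else pen[i] > pen[j]
      if (swap) {
        idx[k] <- j; idx[k + 1] <- i
        swapped <- TRUE
      }
    }
    if (!swapped) break
  }
  idx
}

#' Constrained global optimisation by stochastic ranking evolution strategy
#'
#' A (mu, lambda) evolution strategy with log-normal self-adaptive step
#' sizes and stochastic ranking selection: candidates are bubble-sorted by
#' objective with probability `Pf` (always, when both candidates are
#' feasible) and by constraint penalty otherwise, which lets the search
#' cross infeasible regions while still being pulled toward feasibility.
#' Reproducible for a fixed seed.
#'
#' @param objective function of a parameter vector returning the (finite)
#'   objective value.
#' @param penalty function of a parameter vector returning the non-negative
#'   constraint penalty (0 when feasible). May share computation with
#'   `objective` via memoisation in the caller; it is evaluated at the same
#'   points.
#' @param lower,upper finite bounds on every parameter.
#' @param options an [sresOptions()].
#' @return list with `par` (best feasible-by-rank vector), `value`,
#'   `penalty`, `history` (per-generation best objective/penalty) and
#'   `evaluations`.
#' @export
sresOptimize <- function(objective, penalty, lower, upper,
                         options = sresOptions()) {
  d <- length(lower)
  if (length(upper) != d || any(!is.finite(c(lower, upper)))) {
    stopTyped("invalidArgument", "bounds must be finite and equal length")
  }
  if (any(upper <= lower)) {
    stopTyped("invalidArgument", "zero-width or inverted bounds")
  }
  lam <- options$lambda; mu <- options$mu
  set.seed(options$seed)

  span <- upper - lower
  tau <- 1 / sqrt(2 * sqrt(d)); tau0 <- 1 / sqrt(2 * d)
  # initial population uniform in the box; optional seeded candidates
  X <- matrix(stats::runif(lam * d), lam, d, byrow = TRUE)
  X <- sweep(sweep(X, 2, span, "*"), 2, lower, "+")
  if (!is.null(options$initial)) {
    ini <- options$initial
    if (is.null(dim(ini))) ini <- matrix(ini, nrow = 1)
    k <- min(nrow(ini), lam)
    X[seq_len(k), ] <- pmin(pmax(ini[seq_len(k), , drop = FALSE],
                                 matrix(lower, k, d, byrow = TRUE)),
                            matrix(upper, k, d, byrow = TRUE))
  }
  sf <- if (is.null(options$step_frac)) 1 / sqrt(d) else options$step_frac
  S <- matrix(span * sf, lam, d, byrow = TRUE)  # step sizes

  evalPop <- function(X) {
    ob <- numeric(nrow(X)); pe <- numeric(nrow(X))
    for (i in seq_len(nrow(X))) {
      ob[i] <- objective(X[i, ])
      pe[i] <- penalty(X[i, ])
    }
    list(obj = ob, pen = pe)
  }

  ev <- evalPop(X)
  nEval <- lam
  best <- NULL
  hist <- matrix(NA_real_, options$generations, 2,
                 dimnames = list(NULL, c("objective", "penalty")))

  updateBest <- function(best, X, ev) {
    feas <- which(ev$pen == 0)
    cand <- if (length(feas)) feas[which.min(ev$obj[feas])] else {
      which.min(ev$pen + ev$obj * 0)
    }
    challenger <- list(par = X[cand, ], value = ev$obj[cand],
                       penalty = ev$pen[cand])
    if (is.null(best)) return(challenger)
    better <- (challenger$penalty == 0 && best$penalty > 0) ||
      (challenger$penalty == 0 && best$penalty == 0 &&
         challenger$value < best$value) ||
      (challenger$penalty > 0 && best$penalty > 0 &&
         challenger$penalty < best$penalty)
    if (better) challenger else best
  }
  best <- updateBest(best, X, ev)

  for (g in seq_len(options$generations)) {
    ord <- stochasticRank(ev$obj, ev$pen, options$Pf)
    parX <- X[ord[seq_len(mu)], , drop = FALSE]
    parS <- S[ord[seq_len(mu)], , drop = FALSE]
    pick <- sample.int(mu, lam, replace = TRUE)
    gl <- stats::rnorm(lam)
    Xn <- matrix(0, lam, d); Sn <- matrix(0, lam, d)
    for (i in seq_len(lam)) {
      s <- parS[pick[i], ] * exp(tau0 * gl[i] + tau * stats::rnorm(d))
      s <- pmin(s, span)  # keep steps within a box width
      x <- parX[pick[i], ] + s * stats::rnorm(d)
      # reflect into bounds
      x <- ifelse(x < lower, pmin(upper, 2 * lower - x), x)
      x <- ifelse(x > upper, pmax(lower, 2 * upper - x), x)
      x <- pmin(pmax(x, lower), upper)
      Xn[i, ] <- x; Sn[i, ] <- s
    }
    X <- Xn; S <- Sn
    ev <- evalPop(X)
    nEval <- nEval + lam
    best <- updateBest(best, X, ev)
    hist[g, ] <- c(best$value, best$penalty)
  }
  c(best, list(history = hist, evaluations = nEval))
}
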