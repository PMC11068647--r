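# Generic agent-based co-simulation: exchange contract, monolithic oracle,
# freezing, refinement and determinism.

# two coupled linear ODEs split across agents:
#   dx/dt = -a x + b y   (agent X, exports x, imports y)
#   dy/dt = -c y + d x   (agent Y, exports y, imports x)
makeLinearAgents <- function(a = 0.8, b = 0.3, cc = 0.5, dd = 0.2,
                             x0 = 1, y0 = -0.5, probe = NULL) {
  stepX <- function(state, imports, t0, t1) {
    sol <- deSolve::lsoda(c(x = state[["x"]]), c(t0, t1),
                          function(t, s, p) list(-a * s[[1]] + b * imports[["y"]]),
                          parms = NULL, rtol = 1e-10, atol = 1e-12)
    s <- c(x = unname(sol[nrow(sol), "x"]))
    list(state = s, exports = s)
  }
  stepY <- function(state, imports, t0, t1) {
    if (!is.null(probe)) probe$log[[length(probe$log) + 1]] <- imports
    sol <- deSolve::lsoda(c(y = state[["y"]]), c(t0, t1),
                          function(t, s, p) list(-cc * s[[1]] + dd * imports[["x"]]),
                          parms = NULL, rtol = 1e-10, atol = 1e-12)
    s <- c(y = unname(sol[nrow(sol), "y"]))
    list(state = s, exports = s)
  }
  agX <- agentSpec("X", c(x = x0), "min", stepX, exports = "x",
                   imports = "y", freeze_tol = 0)
  agX$init_exports <- c(x = x0)
  agY <- agentSpec("Y", c(y = y0), "min", stepY, exports = "y",
                   imports = "x", freeze_tol = 0)
  agY$init_exports <- c(y = y0)
  list(agX, agY)
}

test_that("imported values equal the exporter's published values at every
          exchange", {
  probe <- new.env(); probe$log <- list()
  agents <- makeLinearAgents(probe = probe)
  run <- runCosimulation(agents, exchangeSchedule(interval = 0.5, horizon = 5,
                                                  stop_on_equilibrium = FALSE))
  # agent Y consumed exactly the x values agent X published at the same
  # exchange (agents update sequentially within an exchange)
  got <- vapply(probe$log, `[[`, 0, "x")
  published <- run$trajectory[, "x"]
  expect_equal(unname(got), unname(published), tolerance = 1e-12)
})

test_that("co-simulated linear system matches a monolithic solve within 1%", {
  agents <- makeLinearAgents()
  run <- runCosimulation(agents, exchangeSchedule(interval = 0.005,
                                                  horizon = 3,
                                                  stop_on_equilibrium = FALSE))
  mono <- deSolve::lsoda(c(x = 1, y = -0.5), seq(0, 3, by = 0.05),
                         function(t, s, p) {
                           list(c(-0.8 * s[1] + 0.3 * s[2],
                                  -0.5 * s[2] + 0.2 * s[1]))
                         }, parms = NULL, rtol = 1e-10, atol = 1e-12)
  xm <- mono[nrow(mono), "x"]; ym <- mono[nrow(mono), "y"]
  xc <- run$trajectory[nrow(run$trajectory), "x"]
  yc <- run$trajectory[nrow(run$trajectory), "y"]
  expect_lt(abs(xc - xm) / max(abs(xm), 0.01), 0.01)
  expect_lt(abs(yc - ym) / max(abs(ym), 0.01), 0.01)
})

test_that("a settled fast agent is frozen between exchanges", {
  pat <- defaultPatientFixture()
  agents <- makeCardioRenalAgents(pat$params, neutralEffects(), pat$baseline)
  run <- runCosimulation(agents, exchangeSchedule(interval = 2, horizon = 60,
                                                  stop_on_equilibrium = FALSE))
  # at the baseline equilibrium the circulation integrates once and is then
  # skipped at every later exchange
  expect_lte(run$integrations[["circulation"]], 2L)
  expect_equal(run$integrations[["renal"]], nrow(run$trajectory))
  frozen <- run$log[, "circulation"]
  expect_true(all(tail(frozen, -2)))
})

test_that("halving the exchange interval moves equilibrium SBP by less
          than 0.5%", {
  pat <- defaultPatientFixture()
  eff <- applyRegimen("losartan 100")
  a <- simulateToEquilibrium(pat$params, eff, init = pat$baseline,
                             horizon = 14, interval = 4)
  b <- simulateToEquilibrium(pat$params, eff, init = pat$baseline,
                             horizon = 14, interval = 2)
  expect_lt(abs(a$SBP - b$SBP) / b$SBP, 0.005)
})

test_that("identical inputs give identical trajectories", {
  pat <- defaultPatientFixture()
  eff <- applyRegimen("bisoprolol 5")
  a <- simulateToEquilibrium(pat$params, eff, init = pat$baseline,
                             horizon = 10)
  b <- simulateToEquilibrium(pat$params, eff, init = pat$baseline,
                             horizon = 10)
  expect_identical(attr(a, "run")$trajectory, attr(b, "run")$trajectory)
})

test_that("wiring mistakes raise configuration errors", {
  agents <- makeLinearAgents()
  agents[[2]]$exports <- "x"  # duplicate producer
  expect_error(runCosimulation(agents, exchangeSchedule(horizon = 2)),
               class = "configurationError")
  agents <- makeLinearAgents()
  agents[[1]]$imports <- "z"  # never exported
  expect_error(runCosimulation(agents, exchangeSchedule(horizon = 2)),
               class = "configurationError")
})
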