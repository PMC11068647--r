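# Equilibrium detection, baseline calibration, co-simulated convergence and
# the sodium-loading test.

test_that("equilibrium detector accepts constants and cycle-periodic
          oscillations, rejects drift", {
  expect_true(detectEquilibrium(rep(3.2, 100), cycle_length = 10, dt = 1))
  expect_false(detectEquilibrium(seq(0, 5, length.out = 100),
                                 cycle_length = 10, dt = 1))
  t <- seq(0, 20, by = 0.1)
  expect_true(detectEquilibrium(sin(2 * pi * t / 0.8), cycle_length = 0.8,
                                dt = 0.1, tol = 1e-6))
  # a different period is not mistaken for the cardiac cycle
  expect_false(detectEquilibrium(sin(2 * pi * t / 1.3), cycle_length = 0.8,
                                 dt = 0.1, tol = 1e-3))
  # multivariate: every column must satisfy the criterion
  m <- cbind(const = rep(1, 201), drift = seq(0, 10, length.out = 201))
  expect_false(detectEquilibrium(m, cycle_length = 0.8, dt = 0.1))
  expect_error(detectEquilibrium(rep(1, 5), cycle_length = 10, dt = 1),
               class = "invalidArgument")
})

test_that("the calibrated baseline sits inside the reported physiological
          envelopes", {
  eq <- defaultPatientFixture()$baseline
  expect_gt(eq$SBP, 145); expect_lt(eq$SBP, 162)
  expect_gt(eq$DBP, 94); expect_lt(eq$DBP, 107)
  expect_gt(eq$GFR, 74); expect_lt(eq$GFR, 114)
  expect_gt(eq$PRA, 27); expect_lt(eq$PRA, 36)
  expect_gt(eq$AngI, 7.3); expect_lt(eq$AngI, 9.5)
  expect_gt(eq$AngII, 4.3); expect_lt(eq$AngII, 6.3)
  expect_gt(eq$ALD, 160); expect_lt(eq$ALD, 230)
  expect_gt(eq$EF, 55); expect_lt(eq$EF, 75)
})

test_that("equilibrium biomarkers are ordered across the six genotype
          activities", {
  acts <- c(7.0, 8.9, 10.8, 42.3, 54.1, 65.9)
  eqs <- list(); w <- NULL
  for (a in acts) {
    eqs[[as.character(a)]] <- w <- steadyState(defaultParameters(cACE = a),
                                               warm = w)
  }
  AngII <- vapply(eqs, `[[`, 0, "AngII")
  AngI <- vapply(eqs, `[[`, 0, "AngI")
  PRA <- vapply(eqs, `[[`, 0, "PRA")
  d_aff <- vapply(eqs, `[[`, 0, "d_aff")
  P_glom <- vapply(eqs, `[[`, 0, "P_glom")
  expect_true(all(diff(AngII) > 0))
  expect_true(all(diff(AngI) < 0))
  expect_true(all(diff(PRA) < 0))
  # L -> H group contrast: wider afferent vessel, higher capillary pressure
  expect_gt(mean(d_aff[4:6]), mean(d_aff[1:3]))
  expect_gt(mean(P_glom[4:6]), mean(P_glom[1:3]))
  expect_true(all(P_glom[4:6] > max(P_glom[1:3])))
})

test_that("simulating from the baseline reproduces it (idempotence) with a
          frozen fast agent", {
  pat <- defaultPatientFixture()
  eq <- simulateToEquilibrium(pat$params, init = pat$baseline, horizon = 2)
  expect_equal(eq$SBP, pat$baseline$SBP, tolerance = 1e-4)
  expect_equal(eq$V_ecf, pat$baseline$V_ecf, tolerance = 1e-6)
  run <- attr(eq, "run")
  expect_true(run$equilibrium)
  # the circulation integrated once, then froze
  expect_lte(run$integrations[["circulation"]], 2L)
})

test_that("a 10% volume perturbation relaxes back with sodium conserved", {
  pat <- defaultPatientFixture()
  init <- pat$baseline
  init$V_ecf <- 1.1 * init$V_ecf
  init$Na_total <- 1.1 * init$Na_total
  attr(init, "volumes") <- attr(pat$baseline, "volumes") *
    (pat$params$volume$bv_frac * init$V_ecf * 1000 /
       sum(attr(pat$baseline, "volumes")))
  eq <- simulateToEquilibrium(pat$params, init = init, horizon = 14)
  expect_equal(eq$SBP, pat$baseline$SBP, tolerance = 5e-3)
  # terminal net sodium flux is balanced
  u <- renalUpdate(list(Na_total = eq$Na_total, V_ecf = eq$V_ecf),
                   eq$MAP, eq$AT1_signal, params = pat$params, ALD = eq$ALD)
  expect_lt(abs(u$derivatives[["dNa_total"]]),
            2e-3 * pat$params$sodium$phi_sodin)
})

test_that("sodium loading: pass with bounded rise, trivial pass at equal
          intake, fail without natriuretic feedback", {
  pat <- defaultPatientFixture()
  res <- sodiumLoadTest(pat, horizon = 8, interval = 6, window = 60)
  expect_true(res$pass)
  expect_lte(res$delta_SBP, 25)
  expect_gt(res$delta_SBP, 0)

  same <- sodiumLoadTest(pat, elevated_intake = pat$params$sodium$phi_sodin)
  expect_true(same$pass)
  expect_equal(same$delta_SBP, 0)

  # degenerate patient: no pressure-natriuresis or hormonal natriuresis
  p0 <- pat$params
  p0$sodium$g_pn <- 0; p0$sodium$h_at1 <- 0; p0$sodium$h_ald <- 0
  p0$raas$g_renin_vol <- 0
  base0 <- steadyState(p0)
  pat0 <- virtualPatient(p0, base0)
  res0 <- sodiumLoadTest(pat0, horizon = 6, interval = 6, window = 60)
  expect_false(res0$pass)

  pbad <- pat$params
  pbad$sodium$phi_sodin <- 0.25
  expect_error(sodiumLoadTest(virtualPatient(pbad, pat$baseline)),
               class = "invalidArgument")
})
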