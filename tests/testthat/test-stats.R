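# Analyses: sweep shape, KS comparisons, population summaries and
# baseline-response correlations.

test_that("KS comparison handles identity, full separation and matches an
          exhaustive permutation oracle", {
  x <- c(1.1, 2.3, 3.7, 4.2, 5.9)
  same <- ksTwoSample(x, x)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)

  a <- rnorm(10); b <- a + 10
  expect_equal(ksTwoSample(a, b)$D, 1)

  # exhaustive oracle: all C(10, 5) label assignments of the pooled sample
  ksStat <- function(x, y) {
    pool <- sort(unique(c(x, y)))
    max(abs(ecdf(x)(pool) - ecdf(y)(pool)))
  }
  permP <- function(x, y) {
    pool <- c(x, y)
    n <- length(x)
    obs <- ksStat(x, y)
    splits <- combn(length(pool), n)
    hits <- 0
    for (k in seq_len(ncol(splits))) {
      xi <- pool[splits[, k]]
      yi <- pool[-splits[, k]]
      if (ksStat(xi, yi) >= obs - 1e-12) hits <- hits + 1
    }
    hits / ncol(splits)
  }
  set.seed(8)
  for (rep in 1:4) {
    x <- rnorm(5); y <- rnorm(5, mean = rep / 2)
    got <- ksTwoSample(x, y)
    expect_true(got$exact)
    expect_equal(got$p, permP(x, y), tolerance = 1e-12)
    expect_equal(got$D, ksStat(x, y), tolerance = 1e-12)
  }
  # and for unequal small sizes
  for (rep in 1:3) {
    x <- rnorm(4); y <- rnorm(6, 0.8)
    expect_equal(ksTwoSample(x, y)$p, permP(x, y), tolerance = 1e-12)
  }
  expect_error(ksTwoSample(numeric(), 1:3), class = "invalidArgument")
})

test_that("population summaries reproduce a two-pass mean/SD and the full
          reported roster", {
  df <- data.frame(SBP = c(150, 155, 160), DBP = c(95, 100, 105))
  st <- summarizePopulation(df)
  expect_equal(st$mean[st$variable == "SBP"], mean(df$SBP))
  expect_equal(st$sd[st$variable == "DBP"], sd(df$DBP))
  expect_equal(unique(st$n), 3)
  # identical patients have zero dispersion
  same <- data.frame(SBP = rep(150, 4), GFR = rep(90, 4))
  expect_true(all(summarizePopulation(same)$sd == 0))

  pop <- smallPopulationFixture("H", "ID", n = 3, seed = 11)
  st2 <- summarizePopulation(pop, reportRoster())
  expect_setequal(st2$variable, reportRoster())
  expect_true(all(is.finite(st2$mean)))
  expect_true(all(st2$sd >= 0))
  expect_error(summarizePopulation(data.frame()), class = "invalidArgument")
})

test_that("blood pressure rises with ACE activity as a saturation curve", {
  pat <- defaultPatientFixture()
  sw <- aceSweep(pat, grid = c(3, 6, 12, 42.3, 54.1, 60, 65.9, 120))
  expect_true(all(sw$converged))
  expect_true(all(diff(sw$SBP) >= 0))
  expect_true(all(diff(sw$DBP) >= 0))
  # diminishing response to a doubling of activity
  gainLow <- sw$SBP[sw$cACE == 12] - sw$SBP[sw$cACE == 6]
  gainHigh <- sw$SBP[sw$cACE == 120] - sw$SBP[sw$cACE == 60]
  expect_lt(gainHigh, gainLow)
  # genotype spread is narrower in the high-activity band
  spreadH <- sw$SBP[sw$cACE == 65.9] - sw$SBP[sw$cACE == 42.3]
  expect_lt(spreadH, gainLow)
  # consistency with the patient's own equilibrium at its nominal activity
  expect_equal(sw$SBP[sw$cACE == 54.1], pat$baseline$SBP, tolerance = 1e-3)
  expect_error(aceSweep(pat, grid = c(5, 4)), class = "invalidArgument")
})

test_that("placebo change tables are null; active drugs lower pressure", {
  pop <- smallPopulationFixture("H", "ID", n = 3, seed = 11)
  tab <- treatmentChangeTable(pop, list(placebo = character(),
                                        E20 = "enalapril 20"))
  pl <- tab[tab$regimen == "placebo", ]
  expect_true(all(abs(pl$mean_delta) < 0.05))
  expect_true(all(pl$p_endpoint > 0.5))
  en <- tab[tab$regimen == "E20", ]
  expect_true(all(en$mean_delta < 0))
})

test_that("baseline-response correlations: exact linear pairs give 1,
          constant responses are flagged undefined", {
  # synthetic population/outcome pair exercising only the correlation logic
  baselines <- seq(20, 60, length.out = 6)
  pats <- lapply(baselines, function(b) {
    list(baseline = list(PRA = b, AngI = b / 3, AngII = b / 10, DBP = 100))
  })
  pop <- structure(list(patients = pats, label = "synthetic"),
                   class = "population")
  outs <- lapply(baselines, function(b) {
    list(delta = c(DBP = -(2 + 0.1 * b)))  # reduction linear in baseline
  })
  r <- baselineResponseCorrelation(pop, regimen = character(),
                                   outcomes = outs)
  expect_equal(r$r, rep(1, 3), tolerance = 1e-12)
  outs0 <- lapply(baselines, function(b) list(delta = c(DBP = -5)))
  r0 <- baselineResponseCorrelation(pop, regimen = character(),
                                    outcomes = outs0)
  expect_true(all(r0$undefined))
  expect_true(all(is.na(r0$r)))
})
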