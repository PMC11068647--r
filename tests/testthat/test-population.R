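# Demographic sampling, screening and the genotype activity assignment.

test_that("height follows the BMI definition", {
  expect_equal(round(heightFromWeightBmi(80, 29), 1), 166.1)
  expect_equal(round(heightFromWeightBmi(72, 25), 1), 169.7)
  # an implausibly tall draw is screened out
  tall <- list(SBP = 154, DBP = 100, HR = 75, SV = 70, BW = 100, BMI = 25)
  expect_equal(heightFromWeightBmi(100, 25), 200)
  expect_false(passesCriteria(tall))
  expect_error(heightFromWeightBmi(-80, 29), class = "invalidArgument")
})

test_that("screening applies every inclusion and exclusion bound", {
  ok <- list(SBP = 154, DBP = 100, HR = 75, SV = 72, BW = 80, BMI = 29)
  expect_true(passesCriteria(ok))
  expect_false(passesCriteria(modifyList(ok, list(SBP = 185))))
  expect_false(passesCriteria(modifyList(ok, list(DBP = 110))))
  expect_false(passesCriteria(modifyList(ok, list(HR = 55))))
  expect_false(passesCriteria(modifyList(ok, list(HR = 95))))
  expect_false(passesCriteria(modifyList(ok, list(BMI = 37))))
  expect_false(passesCriteria(modifyList(ok, list(BMI = 21))))
  # normotensive draws are not hypertensive enough
  expect_false(passesCriteria(modifyList(ok, list(SBP = 135, DBP = 85))))
  # isolated diastolic hypertension qualifies if SBP > 130
  expect_true(passesCriteria(modifyList(ok, list(SBP = 137, DBP = 95))))
  expect_false(passesCriteria(modifyList(ok, list(SBP = 128, DBP = 95))))
})

test_that("accepted draws follow the truncated sampling distributions", {
  d1 <- sampleDemographics(5, seed = 123)
  d2 <- sampleDemographics(5, seed = 123)
  expect_identical(d1, d2)

  big <- sampleDemographics(2000, seed = 99)
  expect_true(all(vapply(seq_len(nrow(big)),
                         function(i) passesCriteria(as.list(big[i, ])),
                         TRUE)))
  expect_true(all(big$SBP <= 179.5 & big$DBP <= 109.5))
  expect_true(all(big$HR >= 60 & big$HR <= 90))
  expect_true(all(big$BMI > 22 & big$BMI <= 36))
  expect_true(all(big$BH >= 160 & big$BH <= 180))
  expect_gt(mean(big$SBP), 140)
  expect_lt(mean(big$SBP), 179.5)
  expect_lt(sd(big$SBP), 10)       # truncation shrinks the spread
  sexFreq <- mean(big$sex == "male")
  expect_gt(sexFreq, 0.47); expect_lt(sexFreq, 0.53)
})

test_that("group/genotype pairs map to the fixed activity table", {
  expect_equal(assignGroupActivity("H", "II"), 42.3)
  expect_equal(assignGroupActivity("H", "ID"), 54.1)
  expect_equal(assignGroupActivity("H", "DD"), 65.9)
  expect_equal(assignGroupActivity("L", "II"), 7.0)
  expect_equal(assignGroupActivity("L", "ID"), 8.9)
  expect_equal(assignGroupActivity("L", "DD"), 10.8)
  expect_error(assignGroupActivity("M", "II"), class = "invalidArgument")
  expect_error(assignGroupActivity("H", "DI"), class = "invalidArgument")
  # the table equals the genotype split of the two group means
  expect_equal(unname(genotypeAceActivities(54.1)),
               unname(vapply(c("II", "ID", "DD"),
                             function(g) assignGroupActivity("H", g), 0)))
})

test_that("generated subpopulations are reproducible and fully screened", {
  pop <- smallPopulationFixture("H", "ID", n = 3, seed = 11)
  expect_s3_class(pop, "population")
  expect_length(pop$patients, 3)
  for (p in pop$patients) {
    expect_equal(p$cACE, 54.1)
    expect_true(passesCriteria(p$demographics))
    expect_equal(p$penalty, 0)
    expect_true(p$diagnostics$sodium$pass)
    expect_lte(p$diagnostics$sodium$delta_SBP, 25)
    expect_lte(max(p$diagnostics$fit_errors), 0.02)
  }
  pop2 <- generatePopulation(3, "H", "ID", seed = 11)
  expect_identical(populationTable(pop, c("SBP", "AngII")),
                   populationTable(pop2, c("SBP", "AngII")))
})
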