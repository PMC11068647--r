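# Influence functions, the drug catalogue and regimen composition.

test_that("influence factor implements 1 +/- E*d with domain checks", {
  expect_equal(influenceFactor(0.25, 1, "inhibition"), 0.75)
  expect_equal(influenceFactor(0.4, 0, "stimulation"), 1)
  expect_equal(influenceFactor(0.3, 1, "stimulation"), 1.3)
  expect_equal(influenceFactor(0, 1, "inhibition"), 1)
  expect_error(influenceFactor(1, 1, "inhibition"), class = "invalidArgument")
  expect_error(influenceFactor(-0.1, 1, "inhibition"),
               class = "invalidArgument")
  expect_error(influenceFactor(0.3, 2, "inhibition"),
               class = "invalidArgument")
})

test_that("the catalogue holds exactly the six study drugs at their doses", {
  ct <- drugCatalogue()
  expect_setequal(names(ct), c("aliskiren", "enalapril", "losartan",
                               "bisoprolol", "amlodipine",
                               "hydrochlorothiazide"))
  doses <- vapply(ct, `[[`, 0, "dose")
  expect_equal(doses[["aliskiren"]], 300)
  expect_equal(doses[["enalapril"]], 20)
  expect_equal(doses[["losartan"]], 100)
  expect_equal(doses[["bisoprolol"]], 5)
  expect_equal(doses[["amlodipine"]], 5)
  expect_equal(doses[["hydrochlorothiazide"]], 12.5)
  for (d in ct) {
    expect_true(all(d$effects$target %in% effectTargets()))
    expect_true(all(d$effects$E >= 0 & d$effects$E < 1))
  }
})

test_that("regimens are built from name-dose strings, order-insensitively", {
  r1 <- buildRegimen("enalapril 20")
  expect_equal(sum(r1), 1)
  expect_equal(r1[["enalapril"]], 1)
  r3 <- buildRegimen(c("aliskiren 300", "amlodipine 5", "bisoprolol 5"))
  expect_equal(sum(r3), 3)
  r3b <- buildRegimen(c("bisoprolol 5", "aliskiren 300", "amlodipine 5"))
  expect_identical(r3, r3b)
  expect_equal(sum(buildRegimen(character())), 0)
  expect_error(buildRegimen("enalapril 40"), class = "catalogueError")
  expect_error(buildRegimen("metoprolol 50"), class = "catalogueError")
})

test_that("regimen multipliers target the documented mechanisms", {
  none <- applyRegimen(character())
  expect_true(all(none == 1))
  ena <- applyRegimen("enalapril 20")
  expect_lt(ena[["ace_activity"]], 1)
  expect_true(all(ena[setdiff(effectTargets(), "ace_activity")] == 1))
  bis <- applyRegimen("bisoprolol 5")
  for (t in c("heart_rate", "contractility", "renin_secretion",
              "arterial_elastance")) {
    expect_lt(bis[[t]], 1)
  }
})

test_that("combination multipliers equal the product of the monotherapies", {
  ct <- drugCatalogue()
  singles <- c("aliskiren 300", "enalapril 20", "losartan 100",
               "bisoprolol 5", "amlodipine 5", "hydrochlorothiazide 12.5")
  set.seed(10)
  for (k in 1:6) {
    pair <- sample(singles, 2)
    combo <- applyRegimen(pair, ct)
    prod2 <- unclass(applyRegimen(pair[1], ct)) *
      unclass(applyRegimen(pair[2], ct))
    expect_equal(unclass(combo), prod2, tolerance = 1e-12)
  }
  triple <- applyRegimen(singles[1:3], ct)
  prod3 <- Reduce(`*`, lapply(singles[1:3],
                              function(s) unclass(applyRegimen(s, ct))))
  expect_equal(unclass(triple), prod3)
})

test_that("placebo treatment leaves the patient at baseline", {
  pat <- defaultPatientFixture()
  out <- simulateTreatment(pat, character(), duration = 1)
  expect_lt(abs(out$delta[["SBP"]]), 0.02)
  expect_lt(abs(out$delta[["AngII"]]) / pat$baseline$AngII, 1e-3)
})

test_that("equilibrium shifts under each monotherapy match the biomarker
          direction matrix", {
  pat <- defaultPatientFixture()
  base <- pat$baseline
  shifts <- function(drug) {
    eq <- steadyState(pat$params, applyRegimen(drug), warm = base)
    c(SBP = eq$SBP - base$SBP, DBP = eq$DBP - base$DBP,
      PRA = eq$PRA / base$PRA - 1, AngI = eq$AngI / base$AngI - 1,
      AngII = eq$AngII / base$AngII - 1, ALD = eq$ALD / base$ALD - 1)
  }
  al <- shifts("aliskiren 300")
  expect_true(all(al[c("PRA", "AngI", "AngII", "ALD")] < 0))
  en <- shifts("enalapril 20")
  expect_gt(en[["PRA"]], 0); expect_gt(en[["AngI"]], 0)
  expect_lt(en[["AngII"]], 0); expect_lt(en[["ALD"]], 0)
  lo <- shifts("losartan 100")
  expect_true(all(lo[c("PRA", "AngI", "AngII")] > 0))
  expect_lt(lo[["ALD"]], 0)
  bi <- shifts("bisoprolol 5")
  expect_true(all(bi[c("PRA", "AngI", "AngII", "ALD")] < 0))
  hz <- shifts("hydrochlorothiazide 12.5")
  expect_true(all(hz[c("PRA", "AngI", "AngII")] > 0))
  am <- shifts("amlodipine 5")
  expect_true(all(abs(am[c("PRA", "AngI", "AngII", "ALD")]) < 0.01))
  # and every drug lowers both pressures
  for (s in list(al, en, lo, bi, hz, am)) {
    expect_lt(s[["SBP"]], 0)
    expect_lt(s[["DBP"]], 0)
  }
})

test_that("enalapril lowers DBP more at high than at low ACE activity", {
  hi <- defaultPatientFixture(54.1)
  lo <- defaultPatientFixture(8.9)
  dH <- steadyState(hi$params, applyRegimen("enalapril 20"),
                    warm = hi$baseline)$DBP - hi$baseline$DBP
  dL <- steadyState(lo$params, applyRegimen("enalapril 20"),
                    warm = lo$baseline)$DBP - lo$baseline$DBP
  expect_lt(dH, dL)  # both negative; high-ACE reduction is larger
  expect_lt(dH, 0); expect_lt(dL, 0)
})
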