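# Shared fixtures. The default patient's baseline solve is the most
# expensive reusable object; build it once per test run.

defaultPatientFixture <- local({
  cache <- new.env(parent = emptyenv())
  function(cACE = 54.1) {
    key <- paste0("p", cACE)
    if (is.null(cache[[key]])) cache[[key]] <- defaultPatient(cACE)
    cache[[key]]
  }
})

# a tiny generated subpopulation, shared by population-level tests
smallPopulationFixture <- local({
  cache <- new.env(parent = emptyenv())
  function(group = "H", genotype = "ID", n = 3, seed = 11) {
    key <- paste(group, genotype, n, seed, sep = ".")
    if (is.null(cache[[key]])) {
      cache[[key]] <- generatePopulation(n, group, genotype, seed = seed)
    }
    cache[[key]]
  }
})

expect_direction <- function(delta, sign, label) {
  if (sign > 0) {
    expect_gt(delta, 0, label = label)
  } else {
    expect_lt(delta, 0, label = label)
  }
}
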