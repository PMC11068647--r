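Package: raasim
Title: Virtual-Patient Simulation of Blood Pressure Regulation Under Varying ACE Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reduced hybrid model of human blood pressure regulation coupling
    a fast time-varying-elastance circulation (seconds) to a slow
    renal/renin-angiotensin-aldosterone/fluid agent (minutes) by agent-based
    co-simulation. Provides first-order angiotensin conversion kinetics with
    separate ACE and chymase routes, multiplicative pharmacodynamic influence
    functions for six antihypertensive drugs and their combinations,
    constrained virtual-patient generation with a stochastic ranking evolution
    strategy and a sodium-loading acceptance test, genotype-stratified
    population synthesis, and the downstream analyses: ACE-activity sweeps,
    population summary tables, Kolmogorov-Smirnov treatment comparisons and
    baseline-biomarker/response correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    graphics,
    stats,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
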