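---
title: "A reduced cardiorenal model for ACE-activity studies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced cardiorenal model for ACE-activity studies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its model and of the design
choices behind it. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The model

### 1.1 Circulating RAAS

Ang I is converted to Ang II by two parallel first-order routes, ACE
(`cACE`, default 54.1 h⁻¹) and chymase (`cchym`, 1.1 h⁻¹); both constants
are divided by 60 when loaded into the slow agent, whose time unit is
minutes. With first-order kinetics the ACE share of Ang II formation is
`cACE/(cACE + cchym)` — 98 % at the high-activity default and 89 % at the
low-activity value 8.9 h⁻¹ — and this ratio is independent of the state
(mass action), which the test suite asserts exactly.

The rest of the hormonal closure:

* Ang I: production `k_prod · PRA_eff`, removal by conversion plus
  first-order clearance `k_degI`;
* Ang II: production by both conversion routes, clearance `k_degII`;
* renin: the state variable is the pre-inhibition activity; it relaxes
  (τ = 30 min) toward a secretion drive suppressed by AT1 occupancy and by
  volume expansion and scaled by the sympathetic (β-receptor) multiplier.
  Renin inhibition (aliskiren) multiplies both the Ang I production flux
  and the *reported* plasma renin activity, which is why reported PRA falls
  under aliskiren even though secretion rises;
* aldosterone relaxes (τ = 60 min) toward an AT1-driven target.

The clearance and production constants (`k_prod = 0.975`,
`k_degI = 2.714 min⁻¹`, `k_degII = 1.458 min⁻¹`) were derived once,
algebraically, from the requirement that the chain reproduce the
biomarker levels of hypertensive subjects at both reference activities
(PRA ≈ 31 and 64 fmol/mL/min, Ang I ≈ 8.4 and 21.7 fmol/mL, Ang II ≈ 5.3
and 2.5 fmol/mL at cACE = 54.1 and 8.9 h⁻¹ respectively); they were not
revisited afterwards.

### 1.2 AT1 transduction

All downstream responses read the AT1 stimulus (Ang II times the
receptor-blockade multiplier) through a Hill-type occupancy
`σ = AT1ⁿ/(Kⁿ + AT1ⁿ)` with `K = 2.5 fmol/mL`, `n = 2.5`, and respond
exponentially in `σ − σ_ref`. This shape carries two structural
consequences that the study's claims require simultaneously:

* within the high-activity band the occupancy is near saturation, so the
  three H-genotype activities (42.3–65.9 h⁻¹) spread blood pressure less
  than the three L-genotype activities (7.0–10.8 h⁻¹) despite the larger
  absolute Ang II differences — the "lack of association at high ACE
  activity" is a curve-shape consequence;
* a fixed fractional ACE inhibition removes more *absolute* occupancy at
  high than at low baseline activity, so the blood-pressure response to an
  ACE inhibitor grows with ACE activity.

A log-log (power-law) transduction cannot produce both at once — its
relative slope is monotone in the stimulus — which is why the Hill form is
a structural choice, not a tuning convenience. Effector-side deviations
are clamped to ±0.6 around the reference (vascular smooth muscle and
tubular transport saturate); the clamp width was chosen once so that the
low-activity genotype band still responds while extreme stimuli cannot
collapse vascular tone.

### 1.3 Circulation (fast agent)

Six compartments (LV, RV, systemic arteries/veins, pulmonary
arteries/veins) with pressure `E·(V − V₀)`; ventricular elastance runs
between `Ed` and `Es · contractility` under a raised-cosine activation
over the systolic interval `0.388·√T` (capped at `T/2`); valves are ideal
diodes `Q = max(0, ΔP)/R`. Elastances and unstressed volumes were fitted
once (Nelder–Mead) to a hypertensive operating point — 153/100 mmHg,
SV ≈ 72 mL, EDV ≈ 110 mL, EF ≈ 66 %, LV peak pressure ≈ 173 mmHg,
pulmonary pressures ≈ 17.6/11.2 mmHg at HR 75 and 5.0 L blood volume —
and frozen. Unstressed volumes scale per patient with the anthropometric
blood volume so small subjects are not left with collapsed filling. The
Frank–Starling behaviour (higher filling → higher EDV and SV; lower
contractility → higher ESV, lower EF) is emergent and is property-tested,
not imposed.

### 1.4 Kidney and sodium (slow agent)

Arteriolar resistances respond to AT1 occupancy with a small direct
constriction (efferent gain 0.45 > afferent gain 0.05 ≥ 0) plus a
tubuloglomerular-feedback dilation of the afferent vessel (gain 0.45), so
the afferent vessel's *net* response to a rising AT1 signal is dilatory.
This reconciles two constraints: efferent dominance makes glomerular
pressure rise with the AT1 signal, while the TGF term makes the afferent
diameter *increase* from the L to the H group, matching the reported
intraglomerular trend. A myogenic term (gain 1.0 in arterial pressure)
stabilises filtration against pressure changes. Flows are Ohmic:
`RBF = (MAP − P_ven)/(R_aff + R_eff + R_rest)`,
`P_glom = MAP − RBF·R_aff`, `GFR = Kf·(P_glom − P_bowman_onc)` clamped at
zero with a flag. Diameters follow the Poiseuille closure `d ∝ R^(−1/4)`,
reported in µm against reference diameters 13.7/18.7 µm. The effective
filtration margin (`P_bowman_onc = 23.7 mmHg`, `Kf = 3.12 mL/min/mmHg`)
is wider than textbook net filtration pressure; it was widened
deliberately so that filtration is robust over the whole activity sweep —
a reduced-model compromise, flagged as a limitation below.

Sodium balance: `dNa/dt = Φ_sod,in − GFR·[Na]·fe` with the excreted
fraction `fe = fe0 · (MAP/MAP_ref)^7 · exp(−2.2·Δσ) · (ALD/ALD_ref)^(−1.2)`
(pressure natriuresis, AT1 and aldosterone anti-natriuresis); thiazide
action multiplies the *reabsorbed* fraction, `fe_total = 1 − (1 − fe)·F`.
Extracellular volume relaxes toward the osmotic set point
(`d V_ecf/dt = g_osm·([Na] − Na_ref)`), and blood volume is a fixed
patient-specific fraction of it. The pressure-natriuresis exponent 7 and
the volume–renin gain 4 were fixed together so that a sodium loading from
0.1 to 0.243 mEq/min settles with a systolic rise near 20 mmHg (the
acceptance bound is 25 mmHg) while each monotherapy still lowers systolic
pressure by roughly 5–15 mmHg; both behaviours are recomputed, not
asserted, by the tests.

### 1.5 Baroreflex

Heart-rate and contractility commands scale as
`(MAP_ref/MAP)^g` (gains 1.2 and 0.4) around the patient's own set point
(baroreceptor resetting in chronic hypertension), saturating at
physiological extremes (HR 40–180 bpm). This produces the reflex
tachycardia under strong pressure drops and the heart-rate reduction under
β-blockade seen in the treatment suite.

## 2. Co-simulation

The two agents exchange shared variables every 2 model-minutes by default
(sample-and-hold; agents update sequentially within an exchange, the
circulation first). The fast agent is frozen — its integration skipped —
while its imports and exports have stopped moving by more than 1e-4
relative, which is almost always after the first exchange of a settled
phase. Equilibrium is declared when two consecutive 30-minute windows
agree within 1e-3 (relative) for every exchanged variable *and* the net
sodium flux is below 1e-3 of the intake; the flux condition guards
against declaring equilibrium during slow volume creep. A treatment
course is an acute switch of the multipliers followed by a forward run;
the model settles into its new equilibrium within 1–2 model weeks, after
which the state is constant, so the 4-week endpoint equals that
equilibrium. The exchange interval, window, tolerances and horizon are
all arguments; the suite checks that halving the exchange interval moves
equilibrium SBP by less than 0.5 %.

The algebraic solver (`steadyState()`) evaluates exactly the closures used
by the dynamic right-hand sides — the hormone fixed point is a scalar
root problem at fixed volume, the volume is found by a safeguarded secant
on the sodium balance — so its output is the stationary state of the
co-simulation; idempotence is tested.

## 3. The synthetic population

`sampleDemographics()` draws SBP, DBP, HR, SV, BW and BMI from independent
normals — (160, 10), (100, 10), (75, 10), (70, 10) in mmHg/bpm/mL,
(80, 20) kg, (29, 5) kg/m² — selects sex with probability 0.5, computes
height as `100·√(BW/BMI)` (the BMI-consistent reading; the literal
`100·BW/BMI` yields ~276 cm at the means and contradicts the 160–180 cm
criterion), and rejection-samples against the inclusion/exclusion screen
(SBP ≥ 140 and/or DBP ≥ 90 with SBP > 130 and DBP > 80; BMI > 22; height
160–180 cm; excluded: SBP > 179.5, DBP > 109.5, HR outside 60–90,
BMI > 36). Screening precedes any optimisation so no fitting budget is
spent on draws that would be excluded.

`generatePatient()` turns a draw into a model parameterisation. Body
weight, height and sex bound total body water (Watson, age fixed at 50 —
the population carries no age variable) and blood volume (Nadler); ECF is
TBW/3. Twelve patient-level parameters are fitted (intrinsic heart rate,
contractility and ventricular stiffness scales, resting vascular tone,
arterial elasticity, sodium intake within 0.028–0.209 mEq/min, excretion
coefficient, volume set point and blood-volume fraction within the
anthropometric bounds, baroreflex set point, renin and aldosterone
scales). The optimizer is the package's SRES with one refinement: a short
Gauss–Seidel polish of a heuristic seed (heart rate → `HR0`; pressure →
excretion coefficient, because equilibrium pressure is renally
determined; pulse pressure → arterial elasticity; stroke volume →
vascular tone, which trades blood volume at the renally-set pressure)
supplies the first generation's candidates. Four quantities are not
pinned by the haemodynamic targets and are drawn per patient from modest
uniform ranges before refinement: the AT1 receptor sensitivity
(`at1_gain`, the widest range) and the renin, aldosterone and ventricular
stiffness scales. The receptor-sensitivity channel matters structurally:
a patient with a blunted receptor pool runs higher renin/Ang II at the
same effective stimulus *and* sits lower on the occupancy curve, so
baseline RAAS biomarkers correlate positively with the blood-pressure
response to RAAS blockade — heterogeneity placed in the renin scale alone
would produce the opposite sign (higher Ang II, more saturated, smaller
response). This is also what gives subpopulations realistic biomarker and
ejection-fraction spread. Acceptance
requires every target within 2 %, zero constraint penalty, and a passed
sodium-loading test; failures carry a typed reason and are counted.

What the generator does *not* emulate: measurement error and biological
covariance between the sampled traits (draws are independent normals);
age structure; sex-specific physiology beyond the volume bounds;
comorbidity. Passing tests therefore demonstrate internal consistency of
the pipeline under the stated sampling model, not fidelity to any real
cohort.

## 4. Statistics

Two-sample comparisons use the Kolmogorov–Smirnov test (`stats::ks.test`),
exact for `min(n, m) ≤ 10` and asymptotic otherwise; the exact p-value is
verified in the suite against full enumeration of label assignments.
P-values are reported raw with fixed significance markers, matching the
study's reporting convention; no multiplicity correction is applied. The
baseline-biomarker/response correlation is Pearson on (baseline level,
DBP reduction) by default with Spearman available — the choice is a
package decision, as the source convention is unstated.

## 5. Numerical choices

* Fast agent: fixed-step RK4 at 0.25 ms (1 ms inside optimisation loops;
  the difference at the summaries is below 0.01 mmHg), raised-cosine
  activation precomputed per cycle; beat-to-beat periodicity tolerance
  1e-4 on (SBP, DBP, LV SV, RV SV). Ideal-diode valves are the
  zero-crossing limit of the valve events; at this step size an explicit
  root-finder for valve openings changes nothing observable.
* Slow agent: `deSolve::lsoda`, rtol 1e-6, atol 1e-9.
* Steady state: hormone root by `uniroot` in log space (the feedback map
  is monotone, so the fixed point is unique); volume by safeguarded
  secant with residual tolerance 1e-6 (fine) / 1e-3 (coarse) of the
  sodium intake; MAP iteration damped at 0.7.
* Concentrations are clipped at zero with a one-shot warning (chosen over
  log-space integration for simplicity and testability).
* Problem sizes: the acceptance tests generate 10 patients per genotype
  subpopulation (60 in all); the acceptance script regenerates 6 per
  subpopulation and runs every monotherapy and the correlation analysis
  on the pooled high-activity group. The SRES defaults for standalone use
  are λ = 200, μ = 30, 200 generations; patient generation uses the
  seeded desk-scale budget λ = 16, μ = 4, 8 generations, which the
  refinement step makes sufficient (fits land well inside the 2 %
  tolerance).

## 6. Known limitations

* The model is a reduced closure: the full published equation set it
  stands in for resolves oxygen transport, nephron-segment sodium
  handling, bradykinin and much finer vascular structure. Absolute
  population means/SDs and absolute treatment-effect magnitudes are
  therefore out of numerical scope; orderings, signs and contrasts are
  the reproduced content.
* Filtration robustness was bought with a widened filtration-pressure
  margin; GFR responses to RAAS drugs are larger than the "unchanged"
  clinical expectation, though direction-neutral in the reported
  contrasts.
* Chymase activity is genotype-independent, and bradykinin is absent, so
  ACE-inhibitor effects may be overstated at very low ACE activity.
* Treatment is an acute parameter switch; cumulative remodelling under
  chronic therapy is not modelled, so conclusions hold for the 4-week
  horizon only.
* The sodium-loading pass criterion evaluates the new equilibrium; the
  transient overshoot is not bounded separately.
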