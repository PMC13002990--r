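---
title: "Modelling fast and slow alcohol markers with alcotwin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fast and slow alcohol markers with alcotwin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alcotwin)
```

## The problem

In forensic analysis of driving-under-the-influence cases, the "hipflask"
defence claims that alcohol was consumed only *after* an incident. Blood and
breath alcohol (BAC, BrAC) rise and fall too quickly to discriminate such
claims on their own. The slower markers — urine alcohol concentration (UAC)
and the non-oxidative conjugates ethyl glucuronide (EtG) and ethyl sulphate
(EtS) — carry the missing timing information, but extracting it requires a
mechanistic model that describes all markers simultaneously under realistic
intake schedules.

`alcotwin` implements such a physiological digital twin: a multi-compartment
kinetic model of ethanol and its markers, driven by drink, meal and urination
events, with SEM-weighted least-squares estimation, a chi-square
model-rejection test, profile-style uncertainty bounds, population
sensitivity sweeps, and band-based discrimination of competing drinking
scenarios.

## Model structure

The dynamical state has 26 named components (see `stateNames()`), organised
around six compartments:

* **Stomach.** Beverage volume enters at the scheduled drinking rate and
  leaves by gastric emptying, a Michaelis–Menten function of the volume above
  the fasted 0.001 L residual (`VmaxGastric`, `KmGastric`) multiplied by a
  caloric inhibition factor: a decreasing Hill function (exponent `n_kcal`,
  half-saturation `km_kcal`) of the rescaled liquid caloric load
  `Kcal_Liquid / k_kcalscaling`. A bookkeeping state `Kcal_remain` tracks the
  calories still in the stomach; at each drink start, `Kcal_Liquid` is reset
  to it. Ethanol in the stomach partitions into a slow mucosal pool
  (`k_poolIn`/`k_poolOut`) and is attacked by gastric alcohol dehydrogenase
  (Michaelis–Menten in the stomach ethanol concentration, `VmaxADHSto`,
  `KmADHSto`).
* **Intestines.** Emptied ethanol mass is absorbed into the central blood
  compartment at rate `k_EtOHuptake`.
* **Blood.** The blood volume splits into a central compartment (15%), where
  BrAC is expressed, and a peripheral compartment (85%), where BAC is
  measured; they exchange with rate `k_equalize`. Peripheral blood feeds the
  tissue, the liver (`k_equalize_liver`) and the bladder.
* **Liver.** Ethanol is oxidised by ADH and CYP2E1 (two Michaelis–Menten
  terms) and conjugated to EtG and EtS (two more, with much smaller
  capacities). The conjugates diffuse into peripheral blood and are cleared
  into the urine first order (`k_EtG_urine`, `k_EtS_urine`).
* **Tissue and diuresis.** Total body water beyond blood and liver acts as
  the ethanol distribution volume. Ingested water volume transfers to an
  extra tissue-water state, which drives urine production inversely through
  vasopressin; vasopressin synthesis is suppressed by BAC
  (`k_vasopressin_BAC`), producing alcohol-induced diuresis.
* **Bladder.** Urine is tracked as ethanol/EtG/EtS masses plus a volume
  (baseline production 0.01 dL/min). A urination event rescales all masses
  by `0.05/UrineVolume` and resets the volume to the 0.05 dL post-void
  residual, so urine concentrations are continuous across voids.

Observables map states to measured quantities: BAC is peripheral blood
ethanol (mg/dL); BrAC uses the fixed affine breath–blood correlation
`0.840 · (BloodConcCentral/1000) + 0.00367` (g/210 L); UAC is bladder
ethanol mass over urine volume; EtG/EtS are their peripheral blood
concentrations; acetate converts mg/dL to mM by 1/10.2.

### Anthropometric volumes

Blood volume uses the Nadler sex-specific polynomial (height in metres,
cubed); total body water uses the Watson sex-specific linear form (height in
cm) divided by 0.84, which maps Watson water onto the effective ethanol
distribution volume. Liver volume uses Vauthey's weight-linear formula. For
the two reference subjects these give blood volumes of 6.4 L (male, 106.6 kg,
1.86 m, 28 y) and 4.0 L (female, 62.7 kg, 1.69 m, 22 y) with TBW 66.2 L and
37.4 L — the values the model's worked examples print.

```{r volumes}
deriveVolumes(anthropometrics("male", 106.6, 1.86, 28))
deriveVolumes(anthropometrics("female", 62.7, 1.69, 22))
```

### Units

Time is in minutes; stomach volume in L; all body-water, blood and bladder
volumes in dL; masses in mg; concentrations in mg/dL. The ×10 factors in the
volume formulas are L→dL conversions.

### Carried-over sub-models

Five sub-models (stomach ethanol pool, gastric ADH, solid-meal calories,
acetate, PEth) predate this model generation and only their parameters are
specified here. They are implemented as minimal, unit-consistent forms,
isolated in one section of the right-hand side so they can be swapped out:
the mucosal pool exchanges first order with stomach ethanol mass; gastric
ADH is Michaelis–Menten in stomach ethanol concentration; meal calories
enter a solid-kcal state with first-order clearance `k_food_clearance`
(plus a `MaxKcal_Solid` running total); acetate relaxes toward the scaled
hepatic elimination flux at rate `k_acetate` (one parameter doubles as
production scale and clearance, since the parameter table carries no
separate acetate clearance constant); PEth forms from BAC at `k_PEth`, is
cleared at `k_PEth_clearance` and binds reversibly
(`k_PEth_bind`/`k_PEth_release`). A food-present upregulation of hepatic
elimination is exposed as a multiplicative option (`food_elim_factor`,
default 1 = off) because no kinetic form for it is published.

### Two reconciliations worth knowing about

Two places in the published description are internally inconsistent, and the
package resolves them in favour of working physics:

1. **Caloric Hill constant.** The printed gastric-emptying equation reuses
   the volume Michaelis constant in the caloric Hill term, yet the parameter
   table carries a dedicated constant (`km_kcal` ≈ 7219) that appears in no
   printed equation — and with the published values the printed form would
   shut gastric emptying down permanently after any caloric drink.
   `alcotwin` uses `km_kcal` as the Hill half-saturation and `KmGastric`
   only in the volume term.
2. **Urine flux units.** The printed peripheral-blood equation multiplies
   the bladder exchange fluxes (mg/min) by the peripheral blood volume where
   unit analysis requires division; as printed, ethanol mass is not
   conserved. The package divides, and its mass audit closes to integrator
   accuracy (see below).

## Simulation

All events (drink starts/ends, meal starts/ends, urinations) are scheduled,
so integration proceeds segment-wise between event boundaries with hard
restarts — no root-finding is needed. Within a segment the inputs (drinking
rate, beverage ethanol and caloric concentration, meal rate) are constant.
The derivatives are implemented twice: a reference R version and a compiled
C version (the default); the test suite asserts their agreement. Integration
uses `deSolve::lsoda` with default tolerances `rtol = 1e-8`,
`atol = 1e-10`; estimation loops relax these to `1e-6`/`1e-8`, which changes
peak BAC by less than one part in 10^4.

Alongside the dynamical state, the integrator carries cumulative-flux audit
states (ingested ethanol, each elimination channel, net tissue influx,
voided urine). `massAudit()` checks that ingested ethanol equals the sum of
compartment masses, cumulative eliminations and voided urine at every output
time. The tissue compartment is audited by its cumulative net influx rather
than concentration × volume, because its printed rate equation carries no
dilution term while its volume grows with ingested water — concentration ×
volume is simply not the conserved quantity there. With all elimination
channels zeroed, the audit residual stays below 10^-6 (relative) over
720 min; in the full model it closes to integrator accuracy.

## Estimation and the chi-square test

The cost is the SEM-weighted sum of squared residuals over studies,
observables and time points. A model is rejected when the cost exceeds the
inverse chi-square CDF at 1 − α with degrees of freedom equal to the number
of observations (not reduced by the parameter count); α = 0.05 throughout.
Observations below assay detection limits are excluded by a configurable
filter (EtS kept when t > 30 min, EtG when t > 75 min by default).

Parameters are searched in log10 space within the published estimation
bounds, since their values span ten orders of magnitude. The global search
is a bounded differential-evolution (rand/1/bin, reflection at the box),
with a simulated-annealing alternative; both are standard derivative-free
algorithms implemented in the package. Because the cost is needle-sharp on
the log10 scale around well-identified parameters, the global stage is
followed by a bounded local polish (Brent's method for one free parameter,
Nelder–Mead otherwise). The seed is mandatory everywhere randomness enters.

## Uncertainty

A property bound (a parameter, or a prediction at one time point) is its
extremal value subject to the cost staying below the chi-square threshold.
The hard constraint is relaxed into the objective as an L1 penalty with an
offset proportional to the constraint violation; maximisation negates the
property. The penalty is non-smooth, so the penalised problems are solved
with the same global optimiser, warm-started from a feasible point. For
parameter bounds, the feasibility crossing along the bounded coordinate is
then sharpened by expansion-and-bisection — an exact refinement in the
common one-free-parameter case. On closed-form toys (a 1-D quadratic cost;
a weighted linear regression), the bounds match the analytic crossings and
profile envelopes to the optimiser tolerance, and agree with hard-constrained
brute-force grid search.

Prediction bands come in two flavours: the reference per-time-point
penalised optimisation, and a cheaper feasible-ensemble envelope (parameter
draws accepted when their cost is below the threshold) used for scenario
screening. The ensemble band is an inner approximation: it can only
understate, never overstate, the profile band.

## Synthetic studies and calibration

`generateStudy()` emulates the dual-drink study designs: a cohort undergoes
a protocol, blood markers are sampled every 15 min and urine every 30 min,
additive Gaussian noise is applied (per-observable sigma defaulting to 5% of
the simulated peak — the sources publish no noise model, and an SEM-weighted
cost needs a stated one), and per-time-point means with SEM are aggregated.
Optional log-normal inter-subject variability (default CV 15% on the
enzymatic capacities and uptake rate, reflecting the attribution of EtG/EtS
spread to enzymatic variability) can perturb parameters per subject.

Two SEM conventions are available. The default, `sem_mode = "estimated"`,
reports the cohort sample deviation over √n, as published studies do. For
parameter-recovery and calibration experiments the package uses
`sem_mode = "known"` (the true generator sigma over √n): with estimated
SEMs each squared residual at the truth is a t²(n−1) variable with mean
(n−1)/(n−3), which inflates the cost by ~12% at n = 20 and makes the
chi-square threshold over-reject by construction rather than by model error.
With known sigmas the cost at the truth is exactly chi-square distributed,
which is what a calibration check should test. The default cohort size is
n = 20 subjects, comparable to the arms of the dual-drink studies.

What the generator does *not* emulate: assay quantification floors (other
than the exclusion filter), drop-out, non-Gaussian measurement error,
reporting-time rounding, and any systematic deviation between the model
family and reality. Passing recovery tests therefore demonstrates internal
consistency of the estimation machinery, not correctness of the model for
real cohorts.

## Scenario discrimination

Two candidate drinking scenarios are compared through their per-marker
uncertainty bands on a common time grid. The package flags the time regions
where the (optionally margin-inflated) bands are disjoint, clipped to times
after the last drink has ended — the window in which samples can actually be
taken in a forensic setting. Band non-overlap is this package's
operationalisation of "deviating behaviour"; no quantitative threshold is
published, and reports label the rule explicitly. `plausibilityReport()`
flags each measured sample as inside or outside the claimed scenario's band
(widened by 1.96 SEM for measurement error) and returns a three-way verdict
(consistent / inconsistent / indeterminate) with conservative cutoffs; it is
a screening aid, not a likelihood ratio, and deliberately stops short of
evidential quantification.

```{r scenario, eval = FALSE}
an <- readSubject(system.file("extdata", "subject_male.json",
                              package = "alcotwin"))
claim <- buildClaimProtocol("male", an$weight, horizon = 600)
alt <- buildAlternativeProtocol(an$weight, horizon = 600)
ds <- generateStudy(claim, an, seed = 1)
bands <- function(sched, off) {
  sapply(c("yEtOH", "yUAC", "yEtG", "yEtS"), function(m) {
    predictionBand(ds, m, seq(0, 600, 15),
                   scenario = list(schedule = sched, anthro = an),
                   seed = 1 + off, n_ensemble = 12, budget = 40)
  }, simplify = FALSE)
}
deviationIntervals(bands(claim, 0), bands(alt, 1), window_start = 150)
```

## Protocol conventions

The shipped protocol builders encode the source study designs, including
their documented reconstruction assumptions: the first beer dose is consumed
in four 10-min blocks with 5-min sampling gaps over 60 min; 40 v/v% spirits
are diluted with an equal volume of non-alcoholic beverage (volume doubled,
concentration halved); the high-dose vodka window starts 10 min late and
lasts 20 min; the single-drink validation protocol is 0.119 L of 40 v/v%
calorie-free spirits over 30 min with a 500 kcal meal.

Details the sources leave open were fixed once as package conventions: the
second drink starts at 120 min; beverage defaults are beer 5 v/v% at
440 kcal/L, wine 13 v/v% at 830 kcal/L, spirits 40 v/v% at 0 kcal/L (all
overridable); dual-drink protocols include urinations every 30 min (matching
the urine sampling cadence); the alternative single-vodka challenge in the
forensic showcase starts at time 0 over 30 min; meals deliver their calories
uniformly over their duration (default 1 min). Ethanol density is fixed at
789 g/L.

## Numerical choices and degenerate inputs

Event boundaries restart the integrator; output states at an event time are
post-event values. The gastric volume change is clipped at zero so the
emptying rate never turns negative. States are integrated as printed — no
reflection or log transform — and the suite checks they stay above −10^-9.
Zero urine volume makes UAC undefined and raises an error; urination with
the bladder at or below its residual volume warns and does nothing. Zeroed
rate constants are accepted by `simulate()` (conservation experiments need
them) even though `validateParameters()` requires positivity for estimation.
Bound violations by the published defaults (two Michaelis constants sit
outside their own printed bounds) warn rather than reject.

## Problem sizes used by the test suite

The suite exercises the full pipeline at reduced scale, chosen to keep a
complete run around two minutes while leaving every statistical check
well-powered: recovery uses 20 replicates of an 84-point dual-drink design
with a 20-subject cohort; calibration uses 50 replicates of a 50-point
two-marker design; scenario discrimination uses 12-member ensemble bands on
a 15-min grid. Larger designs only sharpen the same comparisons.

## Known limitations

* The five carried-over sub-models are stated assumptions, not published
  kinetics; absolute marker levels (especially EtG/EtS scale and the
  first-pass gastric elimination share) depend on them.
* Degrees of freedom equal the number of observations, as specified for this
  model family; no correction for estimated parameters is applied.
* The ensemble band can understate uncertainty; use the per-time-point
  optimiser when bands feed a consequential comparison.
* Verdicts are band-based screening outputs, not evidence ratios suitable
  for court on their own.
* The model is calibrated to mean cohort behaviour; personalisation enters
  only through anthropometrics unless parameters are re-estimated on
  individual data.
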