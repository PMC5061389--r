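---
title: "Forecasting colonoscopy demand in FIT-based colorectal cancer screening: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting colonoscopy demand in FIT-based colorectal cancer screening: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`crcdemand` is a discrete-event microsimulation of a population-based
colorectal cancer (CRC) screening program that uses the fecal immunochemical
test (FIT) with biennial invitation of men and women aged 50-69, colonoscopy
for positive results, and post-polypectomy surveillance on a European
guideline schedule. Its purpose is capacity planning: forecasting, per
100,000 inhabitants and per calendar year over a 20-year horizon, the
number of colonoscopies generated by the program -- those triggered by a
positive FIT ("index" colonoscopies, including second-look repeats) and
those required by colonoscopic surveillance of people with
intermediate- or high-risk adenomas.

## The simulated process

Every person is simulated individually. The target population starts with
100,000 persons aged 50-69 (ages uniform by default, half men), split into
two alternating invitation waves so that about half the eligible population
is invited each year; from the second year on, a configurable number of
50-year-olds enters annually. Each person carries a time of death sampled
from a gender-specific mortality table; death silently cancels any pending
event.

A routine screening round is a chain of Bernoulli stages, stratified by
gender and age group (50-54, 55-59, 60-64, 65-69) where the underlying data
support it:

1. **Exclusion** before invitation: a stratified probability at the first
   round (all causes), a smaller pooled probability at later rounds
   (medical reasons only: personal or familial history of CRC, adenomas,
   inflammatory bowel disease). Exclusion is permanent.
2. **Opportunistic screening**: invitees reporting a colonoscopy in the
   previous five years are deferred -- four years if the exam was within
   three years, two years otherwise -- without leaving the target
   population.
3. **Participation** (FIT kit pick-up and return, collapsed into one
   stage): a stratified probability at a person's first decision, and
   thereafter a probability conditioned on whether they participated in
   their previous round. Non-participants are re-invited after 2 years.
4. **FIT result**: positivity (hemoglobin at or above the program
   cut-off of 100 ng/mL, which this model treats as documentation -- no
   hemoglobin concentrations are simulated) is stratified at a person's
   first screen, pooled at successive screens. Negatives are re-invited
   after 2 years.
5. **Index colonoscopy**: positives may refuse (stratified probability;
   refusers are re-invited after 2 years). Attended exams draw a result
   category -- normal, low-risk adenomas, intermediate-risk adenomas,
   high-risk adenomas, invasive cancer -- from an empirical distribution
   that differs between initial and successive screens. With probability
   0.123 a second-look colonoscopy (incomplete preparation or resection)
   is added at a uniform time within the following year and counted in the
   calendar year in which it falls.
6. **Routing**: normal exams return to routine invitation after 10 years;
   low-risk adenomas after 2 years; invasive cancer exits the model
   (surveillance of detected cancers is out of scope); intermediate- and
   high-risk adenomas enter surveillance.

Routine invitations stop at age 69 (persons aged 68-69 receive their last
round and age out). People under surveillance are followed to age 79 at
most.

The model deliberately has **no natural-history component**: test results
come from empirical distributions observed in a running program, not from
sensitivity/specificity applied to latent neoplasia. It forecasts demand,
not outcomes, and demand is unconstrained by endoscopy capacity.

## The surveillance scheme

High-risk findings get their first surveillance exam after 1 year,
intermediate-risk after 3 years. The first exam is always attended;
subsequent exams are attended with a run-constant adherence probability.
After an attended exam the default scheme recalls the person in 3 years
whatever the non-cancer finding; two consecutive negative exams discharge
the person back to routine screening (next invitation 5 years later,
subject to the age-69 routine limit), and invasive cancer exits. A missed
exam is rescheduled one recall interval later, so non-adherence delays an
episode rather than ending it; episodes end by discharge, cancer, death or
the age cap of 80. People under surveillance are not simultaneously invited
to FIT screening (a detected adenoma excludes them from the target
population until discharge).

The exact arrows of the published surveillance flowchart are not available,
so the scheme above is a design choice, made once, so that the simulated
surveillance workload reproduces the published program trajectory (rapid
growth from the second year, about 1,000 yearly exams per 100,000
inhabitants after two decades, with late stabilisation). Two alternatives
were examined and rejected because they cannot reach the published level at
the stated adherence (about 52% among current-scenario runs): treating
non-adherence as absorbing caps expected exams per entrant near 2.0, and
discharging low-risk surveillance findings to routine screening thins
episodes further. The whole transition table -- intervals, per-finding
actions, the discharge rule, and the miss policy -- is exposed in the
configuration (`surveillance:` section), so the guideline variant of any
program can be expressed without code changes.

## Parameters, priors and calibration

All screening probabilities live in a YAML configuration
(`inst/extdata/default_config.yaml`); every field can be overridden, and
omitted fields fall back to the packaged defaults. The person-level
registry that fed the original program estimates is not public, so the
packaged defaults are **calibrated stand-ins**: means were chosen so that
the simulated program reproduces the published aggregates -- 44.6k
invitations and 43.8% participation with 6.7% positivity in the first
year, participation rising to ~52% with ~81% successive screens and
positivity falling to ~4.9% after 20 years, 83% colonoscopy uptake among
positives, and the published initial-screen result mix (32.0 / 17.5 /
27.5 / 16.7 / 6.3%). The successive-screen result distribution was
obtained by deconvolving the published mid-horizon result mix (a blend of
initial and successive screens) against the pure initial-screen mix.
Demographic defaults (a linear series of ~7,000-7,400 annual 50-year-old
entrants; Gompertz mortality with `a = 1.17e-5, b = 0.104` for men and
`a = 5.2e-6, b = 0.108` for women, matched to modern Spanish period life
tables) were set the same way. Since strata are known to differ but the
stratum-level values are unavailable, all strata share the field mean by
default; the configuration accepts a vector of eight to differentiate
them.

For the probabilistic sensitivity analysis, each probability treated as
uncertain (exclusions, opportunistic screening, participation, positivity,
refusal) gets an independent Beta prior per stratum with the calibrated
mean and an effective sample size of 500; the result distributions and the
second-look rate are held fixed. Successive-surveillance adherence is
uniform on [0.20, 0.90] and **drawn once per run** -- it is a program-level
property, not an individual one. Each run therefore realises one parameter
set and then simulates every individual decision as a Bernoulli draw.

## Replications, the current scenario, and aggregation

Ensembles use independent L'Ecuyer-CMRG streams spawned from one base
seed; run *i* always gets stream *i*, so results are reproducible and
independent of execution order. The *current scenario* is the subgroup of
runs with 20-year mean participation in [40%, 60%], mean positivity in
[4.7%, 6.8%] and adherence in [35%, 70%] (closed bounds); headline tables
are computed on this subgroup, the sensitivity analysis on the full
ensemble. Yearly tables report across-run means with 95% empirical
percentile intervals (linear interpolation). Note that percentile
intervals describe run-to-run spread; the much narrower intervals printed
in program reports are consistent with standard errors of the across-run
mean, so the two are not directly comparable.

Derived percentages attach to the denominators used in program reporting:
participation to invitations, positivity to participants, colonoscopy
uptake and result categories to first index exams, surveillance findings to
attended exams.

## The demand meta-model

The effect of the three demand drivers is summarised by ordinary least
squares per outcome (index, surveillance, overall colonoscopies) on
run-years: predictors are the year's realised participation and positivity
and the run's adherence (all in percentage points), the year index
`t = 0..19`, each driver's interaction with `t`, and the
positivity-by-participation interaction. Coefficients therefore read as
"extra colonoscopies per year per +1 percentage point". The marginal
effect of positivity at year `t` and participation `p` is
`beta_pos + t * beta_pos:t + p * beta_pos:part`, with a delta-method
standard error; `marginal_effect()` and `effects_grid()` evaluate these
surfaces. Per-year predictor values are used (a 20-year-mean variant can
be obtained by aggregating the design before fitting); no nonlinear terms
are included by design.

## The synthetic registry

`generate_registry()` emulates two rounds of person-level program records
-- the kind of data the real parameters were estimated from -- as
stratified Bernoulli chains with known parameters: round 2 applies
medical-only exclusion, conditions participation on round-1 behaviour, and
uses successive-screen positivity and result distributions for round-1
participants. `estimate_parameters()` inverts the chain with stratified
conditional proportions and exact Clopper-Pearson 95% intervals
(per-category exact intervals for the multinomial result shares), and
`estimates_as_parameters()` feeds the estimates back into the simulator.
This closes the calibration loop -- generate, estimate, re-simulate --
without any real data. Opportunistic screeners are removed from the
participation denominator; registries carry no event times, ages beyond
the stratum label, or mortality, so they validate the estimator, not the
event dynamics.

## Numerical choices and scales

* Event times are continuous (years); calendar tallies use the floor of
  the event time. Sub-year resolution matters for second-look exams and
  staggered invitations.
* Because persons are independent and tallies are keyed only by calendar
  year, the engine processes each person's next event in vectorized
  passes; a 100,000-person, 20-year run costs 20-25 passes (under a
  second) and an identical result is obtained however the event set is
  ordered across persons.
* Time to death is sampled by inverting the piecewise-linear cumulative
  hazard of the configured table; an all-zero hazard yields immortal
  persons (useful in tests).
* Validation rejects any probability outside [0, 1] and any result
  distribution whose mass differs from 1 by more than 1e-9, naming the
  offending field.
* Default problem sizes: the packaged analyses in the test-suite use
  ensembles of up to 560 full-scale runs (100,000 persons); unit tests
  use scaled populations of 2,000-30,000 persons, which keep every rate
  estimate unbiased and simply widen Monte-Carlo noise. The registry
  recovery study uses 200 replicates of 50,000 persons per stratum.

## Known limitations

* Parameter defaults are calibrated to published aggregates, not
  estimated from person-level data; stratum differences are not
  represented by default.
* Successive-screen inputs are pooled across strata, as in the source
  program's reporting.
* The surveillance flowchart is a reconstruction (see above); programs
  with different guideline interpretations should override the transition
  table.
* No natural history, no capacity constraints, no costs, and no spillover
  of program screening onto demand for non-program colonoscopies.
* Mortality is period-table Gompertz without cohort improvement; over a
  20-year horizon this slightly overstates late-horizon deaths.
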