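---
title: "Health expectancies by multistate microsimulation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Health expectancies by multistate microsimulation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

National and regional health plans increasingly track not only life
expectancy (LE) but healthy life expectancy (HLE). The standard HLE
indicator is produced with the Sullivan method, which combines a period
life table with the age-specific prevalence of self-reported good
health from a survey. Surveys are expensive, infrequent and small;
meanwhile health systems already hold exhaustive morbidity records for
their covered populations. `hlemms` implements the alternative: treat a
morbidity classification of the whole population as a set of health
states, estimate annual transition probabilities between those states
(plus death) from two consecutive years of individual records, and
obtain LE and state-specific health expectancies by simulating complete
lifetimes from those probabilities.

The state space is a six-category aggregation of the Clinical Risk
Groups (CRG) health-status classification — 1 Healthy through 6
Dominant and metastatic malignancies — with death appended as an
absorbing state 7. The package does not perform the clinical grouping
itself (a proprietary step that maps ICD/ATC codes to CRG categories);
its inputs start at assigned states, and `aggregate_crg_status()`
collapses the nine raw CRG categories to the six states. The nine
source and six target category labels determine the cross-walk almost
everywhere; the only composite target, state 5, receives both
"dominant chronic disease in three or more organ systems" and
"catastrophic conditions", and the mapping is exposed as a
configurable table so alternatives can be tested.

## The model

The health history of an individual is modelled as a discrete-time
Markov chain over the seven states, with yearly cycles: the state next
year depends only on sex, current age and current state. Transition
probabilities are assumed stationary (constant over calendar time), so
one pair of consecutive observation years identifies them.

**Estimation.** For each sex and each of ten age groups (<1, 1–14,
15–24, …, 75–84, ≥85), the maximum-likelihood estimate of the
transition probability from state *i* to state *j* is the observed
count ratio *s<sub>ij</sub>* / *s<sub>i</sub>*. Estimating at the
age-group level (20 matrices: 10 groups × 2 sexes) rather than by
single year of age keeps every (sex × group × state) cell populated.
The age group is assigned from the baseline age, consistent with
conditioning on the earlier year's state. Deaths during the follow-up
year count as transitions to state 7 regardless of within-year timing.

Two policies handle cells that are nevertheless empty: borrowing the
row from the nearest age group with exposure for the same sex and
state (default; ties resolved toward the younger group), or an
identity row with zero mortality. Either is flagged in the
diagnostics, never applied silently. A `min_cell` threshold (default
30) lists low-exposure cells for inspection without altering the
estimates.

**Interpolation.** The group matrices are attributed to group midpoint
ages and expanded to single years of age 0–90 with natural cubic
splines, entry by entry. Design choices the method leaves open:

* *Midpoints*: 0.5, 8, 20, 30, 40, 50, 60, 70, 80, 90. The open-ended
  ≥85 group is pinned at 90 so the yearly set terminates at a "≥90"
  age. Configurable via the scheme.
* *Infant group*: the [0,1) matrix is used verbatim for age 0 and
  excluded from the spline — infant dynamics are not smooth
  continuations of childhood dynamics.
* *Boundary condition*: natural (zero second derivative) at the first
  and last interpolated midpoints, avoiding manufactured curvature at
  the extremes; ages 1–7 use the spline's natural boundary behaviour
  and ages above 90 reuse the age-90 matrix (constant tail).
* *Row repair*: splined entries are clipped to [0,1] and each living
  row renormalized to sum 1 — the minimal repair of row-stochasticity,
  which entrywise interpolation cannot preserve exactly. Rows whose
  pre-repair sum deviates by more than 1e-3 are logged.

The constant tail deliberately keeps mortality flat above age 90,
which overstates survival at the oldest ages; this is a known
limitation of the group-then-interpolate design, visible as an LE
excess at age 90 in validation against official life tables.
Parametric old-age mortality laws (Gompertz–Makeham) are out of scope.

**Simulation.** `simulate_trajectories()` generates 10,000 lifetime
trajectories per sex by default. Each starts at age 0 in a state drawn
from the empirical composition of the under-1 population, then draws
the next state each year by comparing one uniform pseudo-random number
with the cumulative transition probabilities of the current (sex, age)
row, states ordered 1…7 and ties at cumulative boundaries resolved
upward — a fixed order that makes runs bit-reproducible across
platforms. One stream per sex (seeds `seed` and `seed + 1`), consumed
in a fixed block per trajectory.

**Person-year convention.** A person alive at exact age *x* is
credited one full year in the state occupied at *x*, including the
death year: years lived = age at death + 1. Discrete yearly cycles
imply whole-year accounting; no mid-year (a₀ = 0.5) refinement is
applied inside the simulator. This raises LE by roughly half a year
relative to the standard demographic convention; the life-table
builder therefore defaults to a<sub>x</sub> = 0.5 for standalone
Sullivan runs but uses a<sub>x</sub> = 1 whenever Sullivan output is
cross-checked against the simulator.

Trajectories still alive at `max_attained_age` (default 110, reached
via the constant tail) are censored and flagged; censored trajectories
contribute person-years up to censoring, and a loud warning fires if
more than 1% of trajectories are censored.

**Expectancies.** From the sample, survivors l<sub>x</sub> are the
trajectories with years lived > x, person-years L<sub>x,j</sub> count
trajectories occupying state *j* during age-year *x*, and

e<sub>x,j</sub> = Σ<sub>y≥x</sub> L<sub>y,j</sub> / l<sub>x</sub>.

HLE is the state-1 series e<sub>x,1</sub>; total LE is the sum over
states, and the partition Σ<sub>j</sub> e<sub>x,j</sub> = e<sub>x</sub>
holds exactly at every age (asserted to 1e-9 in the tests).

## Deterministic cross-checks

`analytic_expectancies()` propagates state-occupancy probabilities
age by age with matrix–vector products and applies the same
person-years formula — the exact expectation the Monte Carlo engine
estimates, truncated at the same censoring age. The suite requires the
two to agree within 3 Monte Carlo standard errors at every age and
state; the standard errors themselves are computed exactly from the
chain by a backward second-moment recursion (`mc_sampling_sd()`), so
the check does not degenerate in cells where a finite sample happens
to show no variation.

`sullivan_consistency_check()` exploits stationarity: deriving
q<sub>x</sub> and the cross-sectional healthy prevalence from the
chain's own occupancy and feeding them to the Sullivan path with
matched conventions (a<sub>x</sub> = 1, closed at the censoring age)
must reproduce the multistate healthy expectancy identically; the
suite asserts agreement to 1e-6 (observed: ~1e-15). The life-table
builder is separately validated against a brute-force survival-product
oracle to 1e-12, and the spline expansion against an independently
coded tridiagonal natural-spline solver to 1e-9.

## The synthetic population

No public registry accompanies the method, so `hlemms` ships a
generator whose ground truth is known. `default_study_like_spec()`
describes a population of ≈87,850 persons (scalable) with:

* a general-population age pyramid (ten groups, mild old-age female
  skew);
* baseline healthy shares declining from 93% (<1 year) to 9% (≥85),
  with the residual morbidity mass shifting from acute/minor-chronic
  toward multi-system disease as age rises;
* ground-truth transition matrices in which annual mortality rises
  from ~0.02% (children) to ~7% (healthy, ≥85) and scales with state
  severity (multipliers 1–4), yielding a crude death rate near 1% per
  year and old-age mortality near 5% (75–84) and 14% (≥85);
  persistence is state-dependent (healthy 0.90, transient acute 0.50,
  established chronic 0.85–0.90), recovery and progression decay with
  state distance, and progression strengthens with age.

These are fixture choices made once for plausibility, not a
calibration to any registry; the resulting synthetic LE at birth
(≈79 years female, ≈72 male) is in a realistic range, while the
synthetic HLE is lower than survey-based figures because state-1
occupancy, not self-perception, defines "healthy". Baseline ages are
drawn uniformly within each group (the ≥85 group uses 85–99) — a
simplification; real age heaping and cohort structure are not
emulated, nor are emigration, late registration, classification error
or calendar-time trends. Passing tests therefore demonstrate that the
pipeline recovers known dynamics and that its internal estimators
agree, not that any particular real population satisfies the
stationarity or Markov assumptions.

Reproducibility is bit-exact: one seeded stream per panel, three draws
per record in record order.

## Validation problem sizes

The test suite exercises the pipeline at sizes chosen to balance
statistical resolution against run time: structural checks on a
scale-0.05 panel (~4,400 records); parameter recovery on 50,000
observations per (sex, group, state) cell (6 million records,
recovering every true probability within 0.02, ~9 standard errors of
headroom); stochastic-vs-analytic agreement at the default 10,000
trajectories per sex on two randomized chains; and the acceptance
script runs the full pipeline at scale 1 (87,850 records). The whole
suite completes in well under a minute.

## Known limitations

* Constant-tail mortality above age 90 overstates old-age survival.
* Exactly two observation years: no multi-year panels, no
  continuous-time intensities, no covariate-adjusted transition
  models, no frailty/heterogeneity between individuals.
* Stationarity: period rates are projected over a whole cohort
  lifetime; cohort effects and secular mortality decline are ignored.
* Point estimates only; a replicate-seed variability check is the
  recommended way to gauge Monte Carlo noise (analytic expectancies
  remove it entirely).
* The Sullivan comparison against published survey-based values mixes
  two different concepts of "healthy" (data-based state occupancy vs
  self-perception); large gaps are expected and are a property of the
  concepts, not an error of either estimator.
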