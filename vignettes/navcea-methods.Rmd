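---
title: "Model and methods behind navcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind navcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navcea)
```

## The decision problem

Surgical resection of locally advanced (LARC) and locally recurrent (LRRC)
rectal cancer carries a substantial risk of a tumour-positive circumferential
resection margin (R1), which worsens prognosis. An electromagnetic
image-guided navigation system raises the probability of a tumour-negative
(R0) margin but adds cost: preoperative multiphase CT, a 3D anatomical model,
extra personnel, a hybrid operating room with cone-beam CT, and the
navigation hardware itself. `navcea` implements an early cost-utility
evaluation of adding navigation, from the Dutch healthcare perspective, as a
reusable and fully tested pipeline.

## Model structure

Each strategy (navigated or standard surgery) enters a decision tree on
margin status: with probability $p_{R0}$ the cohort follows the R0 branch,
otherwise the R1 branch. Each branch is a Markov cohort model with
three-month cycles over a three-year horizon (12 cycles) and states

* **disease-free** (DF) — everyone starts here;
* **progressive disease** (PD), split into two *tunnel* states by the time of
  entry: progression during the first year, or during the second or third
  year, because the observed risk of dying after progression differs sharply
  between the two;
* **death**, absorbing.

In cycle $k$ (year class $y = \lceil k/4 \rceil$) the disease-free state
loses $p^{\text{prog}}_{m,y}$ to the PD pool (the year-1 tunnel if $y = 1$,
otherwise the year-2/3 tunnel) and a constant background mortality to death;
each tunnel loses its entry-class death probability per cycle. Transitions
are applied simultaneously from start-of-cycle occupancies, so occupancy mass
is conserved exactly (the test suite asserts conservation to $10^{-12}$ and
agreement with an independently coded dense transition-matrix oracle to
$10^{-10}$).

Background mortality applies in the disease-free state only: the death
probabilities of the tunnel states were estimated from all-cause deaths after
progression in the source cohort and therefore already include background
risk, and the configured value is itself a national all-cause figure matched
to the cohorts' mean ages. It enters as a single per-cycle constant; the
three-year horizon is too short for age-updating to matter at these
magnitudes.

## Inputs

All inputs live in YAML configurations (`navcea_example("larc")`,
`navcea_example("lrrc")`): margin rates per strategy, per-cycle transition
probabilities by margin and year class, state and transition costs, the
intervention costs, utilities, discount rates, the willingness-to-pay
threshold and the value-of-information settings. Monetary values are stored
as plain decimals (the source tables use European formatting, e.g.
`€10.970` = 10970 and `€4.644,28` = 4644.28; decoding happened once when the
configurations were authored).

The printed per-cycle probabilities are the canonical model inputs. The
observed event counts behind them are stored alongside, and
`observed_to_cycle_prob()` implements the standard rate transform
$1 - \exp(-rt)$ with $r = -\log(1 - c)/t_{\text{obs}}$ for an observed
chance $c$. `check_fixture_consistency()` reports, cell by cell, whether the
stored counts re-derive the canonical probability. Several cells do not
(e.g. the LARC R0 year-1 cell 29/85 converts to 0.0991, not the canonical
0.103; the LRRC R1 year-1 cell 11/20 converts to 0.181, not 0.252, although
an at-risk set of 16 — consistent with removing patients with pre-operative
limited metastases from the risk set — reproduces it exactly). The at-risk
corrections used by the source are not stated, so the canonical values are
used as published and the discrepancies are reported, never "corrected".

```{r consistency}
params <- load_parameter_set(navcea_example("larc"))
check_fixture_consistency(params)
```

## Accumulation and discounting conventions

Cycle $k$ accrues state costs (DF occupants at 492 EUR, PD occupants at 585
EUR per cycle), a one-time progression cost on the cycle's DF-to-PD inflow,
utilities (0.70 for every alive occupant in cycle 1, reflecting the impact
of surgery itself; thereafter 0.85 for DF and 0.77 for PD) times the
quarter-year cycle length, and life-years. Cycle-$k$ amounts are discounted
by $(1+r)^{-(k-1)/4}$ at 4% per year for costs and 1.5% for effects (Dutch
guideline rates); the intervention cost (surgery 10970 EUR, plus 3388 EUR
for the navigation addition in the navigated arm) is charged up front,
undiscounted. No half-cycle correction is applied. Life-years are discounted
at the effect rate, like QALYs; `markov_conventions()` exposes an
undiscounted alternative and an alternative discount exponent $k/4$, since
the source leaves both unstated.

One convention cannot be pinned down at all from the published material:
whether a cycle's accruals are counted on the cohort *entering* the cycle or
on the cohort *after* the cycle's transitions. The two choices bracket the
published results in an irreconcilable way:

* counting **after** transitions (`count_method = "end"`, the default)
  reproduces the published per-strategy totals — costs, QALYs and life-years
  of both arms in both indications — to about 1–4%;
* counting the **entering** cohort (`count_method = "beginning"`) shifts the
  between-arm contrast by one cycle and reproduces the published
  *incremental* quantities — incremental QALYs (0.0230 for LARC and 0.05515
  for LRRC, as implied by the exact collinearity of the four published
  ICER/navigation-cost pairs per indication), the scenario ICERs and the
  navigation-cost thresholds — to about 1–3%, while pushing the per-arm
  levels 4–7% high.

No accrual rule can satisfy both sets of published numbers simultaneously
(any rule between the two brackets misses both), so the published levels and
increments are mutually inconsistent at the few-percent level — consistent
with the source's own text-versus-table disagreement of about 2% for the
LRRC totals. The package's acceptance tests therefore check level-type
quantities under the default convention and increment-type quantities under
`"beginning"`, and both conventions are first-class options everywhere.

## Probabilistic sensitivity analysis

Uncertain parameters carry `(family, mean, se)` distribution specifications:
beta for probabilities and utilities, gamma for costs, fitted by the method
of moments (`beta_from_moments()`, `gamma_from_moments()`; infeasible
moments are rejected with an error naming the parameter). Parameters with no
published standard error (only the background mortality in the packaged
configurations) are fixed.

`run_psa()` samples every uncertain parameter independently — no correlation
structure is imposed, since none is published — in a single documented order
(the row order of `tidy()` on the parameter set) from one seeded generator,
so results are bit-reproducible given the seed. Within a draw, parameters
shared between the strategies (transition probabilities, state and
transition costs, the surgery cost, utilities) take one common value for
both arms; the margin rates are drawn per arm and the navigation addition is
charged only to the navigated arm. The default 2000 draws match the source
analysis; the quadrant fractions of the cost-effectiveness plane and the
acceptability curves (`ceac()`, ties credited to the incumbent standard
surgery) are computed from the stored draw table.

## Deterministic sensitivity, scenarios, threshold

`tornado()` varies one parameter at a time over mean $\pm 1.96$ standard
errors — a 95% normal approximation, clipped to $[0,1]$ for probabilities
and utilities and to $[0,\infty)$ for costs — holding everything else at
base case. Whether the source used these limits or distribution percentiles
is not stated; the half-width is configurable. The navigation-cost bar is
exactly linear: its width equals the input range divided by the incremental
QALYs, which the tests assert to $10^{-9}$.

Scenarios substitute the navigation-addition cost distribution: 6363 EUR
when a hybrid operating room must first be built, 1670 EUR when the system's
utilisation rises from 12% to 50% of capacity, and 4644.28 EUR for both
combined. Scenario runs are plain base-case runs with the constant
substituted; the scenario distributions also flow into scenario PSA runs
(`run_psa(..., scenario = "utilization_50")`).

`threshold_navigation_cost()` returns the maximum incremental cost per
patient at which the ICER equals the willingness to pay — exactly
$\lambda \, \Delta Q$ under the no-half-cycle convention — and maps it to
the corresponding navigation cost through the linear cost relationship.

## Value of information

`evpi()` is the textbook estimator: the mean over draws of the best
strategy's net monetary benefit minus the best mean net monetary benefit,
non-negative by construction. The beneficiary population discounts ten
annual incidence cohorts (1384 LARC, 250 LRRC patients per year) at 4%, the
first cohort undiscounted by default (the alternative is a flag, since the
convention is unstated).

For EVPPI no estimation method is published, so the package provides two:

* a nested two-level Monte Carlo estimator (`evppi_group()`, default
  500 x 500 draws) — the outer loop samples the group of interest, the inner
  loop the complement; one inner sample is reused across outer iterations,
  which reduces variance and makes the estimate exactly zero for groups
  without uncertainty;
* a single-loop regression estimator (`evppi_regression()`) that smooths the
  per-draw incremental net monetary benefit on the group's sampled values
  with additive splines, as an independent cross-check. The tests require
  the two to agree within combined Monte Carlo error.

One structural consequence of sharing parameter draws across arms deserves
emphasis: parameters that are common to both strategies and enter the two
arms near-symmetrically (utilities, state costs, the surgery cost) almost
cancel out of the incremental net monetary benefit, so their partial
information value is necessarily close to zero, and the very wide transition
probability uncertainties dominate the group ranking on the LRRC
configuration under both estimators. A ranking that puts the margin rates
first, or attributes material value to utilities and treatment costs, is
only obtainable if the arms' shared parameters are sampled independently —
which the package deliberately does not do, because sharing is what makes
the acceptability-curve results reproduce. The EVPI for LARC is computed but
reported with a note, since standard surgery is preferred at the threshold
in the LARC base case.

## Synthetic cohorts and parameter recovery

`generate_cohort()` is the generative twin of the cohort model: margins are
Bernoulli draws per arm, progression and background death compete cycle by
cycle through a single uniform draw per patient-cycle (so the marginal
per-cycle probabilities equal the model's exactly), and death after
progression is geometric in the entry class's per-cycle hazard. An optional
fraction of patients is forced into progression in cycle 1, emulating
pre-operative limited-metastasis patients. `summarize_counts()` then reports
the cohort the way the estimation workflow expects it: margin proportions,
progression events per margin and year class with year-on-year nested risk
sets, and deaths after progression by entry class over fixed post-entry
windows (two years for year-1 entrants; one year for year-2/3 entrants
restricted to those with a full year of potential follow-up), chosen so that
the annualisation in `observed_to_cycle_prob()` is exact in expectation
under the model's constant per-cycle hazards.

The headline recovery property — generate at $n = 10^5$, summarise, convert,
and recover every cohort-estimated transition parameter within three
standard errors — is run with background mortality switched off, because
that parameter is nationally sourced rather than cohort-estimated and its
competing-risk contamination of the annual progression windows is a property
of the reporting format, not of the estimator. The synthetic cohorts emulate
the statistical structure the analysis assumes — constant per-cycle hazards
within year classes, no covariates, no correlation between margin status and
anything but the configured probabilities — and deliberately not the
messiness of the real retrospective cohort (variable follow-up, at-risk
corrections, double surgeries), so passing recovery tests validate the
estimation pipeline, not the clinical data.

## Problem sizes and numerical choices

The shipped tests run the full pipeline at the source's scale where that is
cheap (2000-draw PSAs, 500 x 500 nested EVPPI, $10^5$-patient recovery
cohorts; the engine is vectorised across draws, so all of this completes in
seconds) and at reduced scale for pure invariance checks. Ties in the
acceptability curve go to standard surgery; the ICER is returned as `NA`
with a dominance label, never as a silent infinity, when the incremental
QALYs are zero; competing exit probabilities exceeding one abort with the
state and cycle named; and beta-infeasible moment pairs abort at
configuration load, not at sampling time.

## Known limitations

The model inherits the source analysis's scope: two margin categories (no
R2), a three-year horizon, no utility decrement trajectory beyond the
first-cycle value, costs from Dutch tariffs and expert elicitation, and no
patient covariates. The published per-arm totals and published increments
cannot both be hit by one convention (see above), the published count cells
cannot all be re-derived from the published denominators, and the published
EVPPI ranking is unattainable under arm-shared sampling; all three are
surfaced by the package rather than hidden, and the corresponding checks in
the acceptance suite document the residual gaps.
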