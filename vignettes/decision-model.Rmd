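---
title: "A three-state Markov model for first-line immunotherapy in advanced NSCLC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-state Markov model for first-line immunotherapy in advanced NSCLC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovcea)
```

## The decision problem

`markovcea` models the cost-effectiveness, from a US payer's perspective, of
first-line nivolumab plus ipilimumab against platinum-doublet chemotherapy
in advanced non-small-cell lung cancer (NSCLC) without targetable driver
alterations, in three populations stratified by tumour PD-L1 expression
(≥50%, ≥1%, <1%). The survival inputs are Weibull extrapolations of the
CheckMate 227 overall-survival and progression-free-survival curves; the
remaining inputs (utilities, per-cycle prices, grade ≥3 adverse-event risks
and management costs, subsequent-therapy mixes) ship as three bundled
scenario files. The bundled scenarios reproduce, within the tolerance one
can expect given unreported modelling conventions, the published base-case
analysis from which their parameter tables derive; this vignette documents
every convention we had to fix ourselves and why.

## Model structure

Three health states: progression-free (PFS), progressed disease (PD), and
death. The cohort starts in PFS, cycles are 6 weeks (42 days), and the
horizon is 20 years — 174 cycle-start evaluations (cycle 0 through 173).
Costs, life-years and QALYs are all discounted at 3% per year with the
per-cycle factor $(1+r)^{-t\,c/365.25}$ for cycle index $t$ and cycle
length $c$ in days.

Survival in each arm is governed by two Weibull curves,
$S(t) = \exp(-\lambda t^{\gamma})$ with time measured in model cycles. The
probability that an event occurs during cycle $t$, conditional on being
event-free at its start, is

$$p(t) \;=\; 1 - \frac{S(t+1)}{S(t)} \;=\; 1 - \exp\!\big(\lambda t^{\gamma} -
\lambda (t+1)^{\gamma}\big),$$

applied to the OS curve for death and to the PFS curve for leaving the
progression-free state.

**Transition structure.** The published inputs provide an OS and a PFS
curve per arm and nothing else, which under-determines the state
transitions. We use the standard construction for that input set: the
OS-derived death probability applies to *both* alive states at the same
cycle index, and the PFS→PD flow is the excess of the PFS event probability
over the death probability, floored at zero. Two useful identities follow:
the PFS occupancy column equals $S_{PFS}(t)$ wherever the progression
hazard dominates the death hazard, and $1-\text{dead}(t)$ equals
$S_{OS}(t)$ always — the model is a partitioned-survival analysis expressed
as a Markov chain, which is what the trace-consistency tests assert. The
alternative in which deaths occur only from the PD state reproduces the
published arm-level life-years more closely for the chemotherapy arm but
overshoots the immunotherapy arm by ~40% and distorts every incremental
quantity; we document this and keep the OS-anchored construction, which
reproduces all published *incremental* results within ±13%.

State membership is counted at cycle start (cycle 0 contributes fully);
`half_cycle_correction = TRUE` switches accrual to trapezoid occupancy and
is off by default, matching the convention of the software the reference
analysis was built in.

## Costs

All prices are USD per 6-week model cycle; they already cover every
administration inside the cycle (e.g. the nivolumab price covers three
2-weekly doses, the pemetrexed price two 3-weekly doses).

* **Active treatment (PFS state).** The immunotherapy arm accrues the
  nivolumab + ipilimumab price while progression-free, for at most
  `max_cycles = 22` cycles (~2.5 years). The trial protocol capped
  immunotherapy at 2 years while the reference analysis states only
  "until progression"; neither choice reproduces the published intervention
  arm total (a hard 2-year cap undershoots it by ~20%, no cap overshoots by
  ~30%), so the duration was calibrated once against that total and left
  alone. It is an ordinary scenario parameter
  (`intervention$treatment$max_cycles`) for anyone who prefers the strict
  trial rule.
* **Chemotherapy arm.** Two induction cycles (= four 3-weekly doublet
  administrations) of the histology-weighted doublet price — non-squamous
  patients (70.8% or 75.3% by population) on pemetrexed + platinum,
  squamous on gemcitabine + platinum, platinum averaged 50/50 over
  carboplatin and cisplatin (the split is unreported; the whole effect is
  under \$60/cycle) — followed by pemetrexed maintenance weighted by the
  non-squamous share while progression-free.
* **Administration, imaging, laboratory.** Administration accrues with
  active treatment; CT imaging accrues at its 6-weekly price in PFS and
  prorated to the 9-weekly post-progression interval (price × 6/9) in PD;
  laboratory costs accrue in both alive states.
* **Adverse events.** The burden is incidence × management cost per event
  summed over the arm's grade ≥3 profile (`ae_burden()`). By default it
  accrues per cycle in the PFS (on-treatment) state; `ae_accrual =
  "one_time"` charges it once at model entry instead. The per-cycle default
  was chosen because the published comparator-arm totals are unreachable
  under one-time accrual; both conventions are tested.
* **Subsequent therapy (PD state).** Each item contributes proportion ×
  price per cycle of PD residence — including radiotherapy, i.e. the whole
  mix is a blended per-cycle PD-state cost. Items can be marked `accrual:
  one_time` to charge on the newly-progressed fraction instead; this is the
  more natural reading for a course-priced item like radiotherapy, but the
  published totals again require the blended per-cycle treatment, so that
  is the default.
* **Treatment discontinuation.** The published table reports
  discontinuation proportions without stating their computational role;
  they are stored, not applied. `apply_discontinuation = TRUE` uses them as
  a multiplier on active-treatment drug cost.

The dose calculators (`carboplatin_dose()` via Calvert and
Cockcroft–Gault, `bsa_dose()`) are audit helpers for checking per-cycle
prices against unit doses; base-case costing uses the price table directly
because per-mg prices are not part of the bundled inputs.

## Utilities

Progression-free utility is arm-specific (0.784 immunotherapy, 0.693
chemotherapy, from trial patient-reported outcomes); the progressed state
uses 0.473 in both arms. QALYs weight the occupancy columns by these
utilities, in years, discounted like costs.

## Sensitivity analyses

Every parameter carrying a published range enters both the one-way
(tornado) and probabilistic analyses, addressed by dot paths such as
`prices.nivolumab` or `comparator.ae.anemia`. Ranges are treated as
approximate 95% intervals: `sd = (max − min)/3.92`, with `range_divisor`
exposed for the `/4` convention. Probabilities and utilities draw from
method-of-moments beta distributions, costs from gamma; zero-width ranges
degenerate to point masses, which is how the PSA-reproduces-base-case test
works. Draws are independent (no correlation structure is published) and
all generated up front from one seeded stream, so a seed fully determines
a PSA. Survival parameters are *not* varied — the published table assigns
them no range or distribution — and this is the main reason our PSA is
much more confident than the published one: the published 65.3/55.2/43.1%
cost-effectiveness probabilities imply an ICER standard deviation around
\$110k, whereas propagating only the tabulated ranges supports roughly
\$20k, so we obtain ~99.9/90.7/15.6%. We report what the stated inputs
imply rather than inflating distributions to match.

`threshold_price()` finds, by bisection to 0.1%, the smallest fractional
cut of one price-table entry that brings the ICER to the willingness-to-pay
threshold. The cut applies everywhere the drug appears — acquisition in the
intervention arm *and* post-study use in the comparator arm — as an actual
price change would; this reproduces the published ~21% (nivolumab) and
~24% (ipilimumab) reductions for the PD-L1 <1% population almost exactly,
whereas cutting only the acquisition cost gives ~14%.

## Survival fitting and synthetic data

`fit_weibull()` recovers $(\gamma, \lambda)$ from digitized Kaplan–Meier
coordinates by ordinary least squares on the complementary log-log
transform $\log(-\log S) = \log\lambda + \gamma\log t$; points with $S = 1$
or $t = 0$ carry no information on that scale and are dropped, and ties in
time are rejected. With at-risk numbers available, `interval_weighted`
weights the regression by reconstructed interval event counts.

`simulate_km()` emulates the digitization pipeline the fitting stage
assumes: inverse-CDF Weibull event times, administrative censoring at a
fixed cycle, the product-limit estimator evaluated on a reporting grid, and
additive digitization noise (default sd 0.005, always below 0.05) with an
isotonic repair so the curve cannot increase. What it deliberately does not
emulate: informative censoring, reporting grids coarser at the tail,
at-risk-table rounding, and reader bias in curve extraction — so passing
recovery tests demonstrate estimator correctness under the stated noise
model, not robustness to real digitization artefacts. At 500 simulated
patients the median parameter-recovery error is ~8%, which is why the
recovery tests assert a 10% bound at that size (and a decreasing median
error over 100 → 500 → 2000 patients).

## Numerical choices

* Trace length: `floor(horizon_years × 365.25 / cycle_length_days) + 1`
  cycle-start evaluations; 174 for the defaults.
* `weibull_rmst()` uses the closed form via the regularised incomplete
  gamma function; tests cross-check it against adaptive quadrature.
* The PFS→PD floor `max(0, p_leave − p_die)` handles curve crossings
  (possible late in the horizon for the immunotherapy arms) without
  negative flows.
* Undefined ICERs (dominance, zero QALY difference) are reported as labels,
  never as signed infinities.
* Bisection tolerance for threshold prices is 0.001 on the reduction
  fraction.

## Known limitations

* Arm-level life-year totals sit 10–35% below the published ones in all
  six arms; the published values exceed what the published OS Weibull
  parameters can generate under any mortality structure anchored to the OS
  curve, so exact arm-level reproduction is impossible from the stated
  inputs. Incremental results, the decision at \$150,000/QALY, the ICER
  ordering across populations, and the threshold prices all reproduce.
* The PSA understates the published uncertainty for the reason given
  above.
* No subgroup analyses, no PD-L1 1–49% population, no high-TMB bundled
  scenario (its survival and toxicity inputs are not part of the bundled
  tables; a user-supplied scenario file covers that use case), and no
  EVPI computation.

## A worked run

```{r, eval = FALSE}
scenario <- builtin_scenarios("pdl1_ge50")
run <- run_cea(scenario)
results_table(run)
nmb(run$comparison, wtp = 150000)
tornado(scenario)
run_psa(scenario, n_draws = 1000, seed = 1)
threshold_price(builtin_scenarios("pdl1_lt1"), "nivolumab")
```
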