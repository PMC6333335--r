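---
title: "A decision-analytic model for targeting risk-score testing and statin therapy in CHD prevention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-analytic model for targeting risk-score testing and statin therapy in CHD prevention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chdstrat)
```

## The decision problem

A healthcare system must decide, for every patient aged 45 or more, whether
to measure a traditional clinical risk score (TRS), a polygenic genetic risk
score (GRS), both, or neither — and, given the information obtained, whether
to start statin therapy as primary prevention of coronary heart disease
(CHD). The patient's state of health is modelled as a static binary
variable: will or will not the patient suffer a CHD event within the next 10
years. All belief about that state is carried by a single number, the
patient's current 10-year event risk; tests refine that belief, treatment
acts on it.

The objective is population expected **net monetary benefit**,

$$\mathrm{NMB} = \mathrm{QALYs} \times \lambda - \mathrm{Costs},$$

with health outcomes in quality-adjusted life-years, costs in 2015 Euros,
and $\lambda$ the societal willingness-to-pay threshold (50,000 €/QALY in
the base case). A single monetary objective makes the sequential testing
problem a plain single-objective dynamic program.

## End-state valuation

Every path through the decision tree terminates in one of four states:

| state | meaning                        |
|-------|--------------------------------|
| I     | no CHD event, untreated (true negative)  |
| II    | no CHD event, treated (false positive)   |
| III   | CHD event, untreated (false negative)    |
| IV    | CHD event, treated (true positive)       |

`endstate_values()` turns the parameter set of `econ_params()` into
discounted cost, QALY, and NMB values for the four states. The conventions:

* **Horizon and discounting.** 10 years, 3\%/year on both costs and health.
  Annual flows (statin 53 €, monitoring 173 €, secondary prevention 451 €,
  quality-of-life weights) are end-of-year payments valued by
  `annuity_factor()`; the 10-year factor is
  $\sum_{t=1}^{10} 1.03^{-t} = 8.5302$. A fractional terminal year is
  pro-rated and discounted at its end time, and mid-horizon intervals are
  valued by complement, which keeps the factor additive over abutting
  intervals. One-off event flows are discounted at the expected event time
  exactly ($1.03^{-5.75}$).
* **Event timing.** Conditional on an event occurring within the horizon,
  it is placed at its expected time, 5.75 years.
* **Event severity.** An event is fatal with probability 0.22 (QoL drops to
  zero afterwards; fatal-event cost 2,417 €). A non-fatal event costs
  19,860 € (the event-count-weighted mean of acute plus one-year follow-up
  costs across MI, unstable AP, CABG and PTCA categories — see
  `weighted_event_cost()`), causes a one-year quality-of-life loss of 0.147,
  and puts the survivor on secondary prevention (451 €/year) until the end
  of the horizon.
* **Treatment semantics.** "CHD" end states mean the patient *would* suffer
  an event absent treatment. Statin therapy averts the event with
  probability 0.27 (the relative risk reduction), so state IV is a mixture:
  with probability 0.27 the patient follows the treated no-event path, and
  otherwise the event path with primary prevention (and its 0.002/year
  quality-of-life decrement) accruing until the event time, where it stops
  for fatal and non-fatal branches alike. This mixture reading is the only
  one under which the published state-IV cost and QALY values are
  recoverable from the input parameters.
* **Quality of life.** The CHD-free weight is 0.903, the population-weighted
  average of the age-band 15D estimates in `qol_by_age_table()`. The
  rounded 0.90 headline value does not reproduce the published discounted
  QALYs; the weighted average does, to within 0.05\%.
* **Signs.** Costs are reported negative (as in the source table); NMB is
  computed as `qaly * wtp + cost` on that convention. Internal arithmetic is
  unrounded; rounding is for display only.

The exact discounting convention for mid-horizon flows (year-boundary
versus continuous) is not pinned down by the published numbers; the
conventions above reproduce the published end-state table within 0.4\% on
costs and 0.1\% on QALYs and NMBs, which the acceptance tests assert at
tolerances of 1\% and 0.5\%.

The final-stage decision has a closed form: treating is optimal exactly when
the current risk exceeds

$$p^\* = \frac{\mathrm{NMB}_I - \mathrm{NMB}_{II}}
  {(\mathrm{NMB}_I - \mathrm{NMB}_{II}) + (\mathrm{NMB}_{IV} - \mathrm{NMB}_{III})},$$

about 0.186 at base case (`treatment_threshold()`).

## Bayesian risk updating

Test accuracy is encoded as binned conditional result distributions
$P(\text{result} \mid \text{CHD})$ and $P(\text{result} \mid \text{no CHD})$
(`likelihood_table`). Observing bin $b$ updates the risk by Bayes' rule
(`posterior_update()`); the expectation of the posterior over the marginal
result distribution (`marginal_result_prob()`) equals the prior — the
martingale property the test suite checks exactly. The two tests are taken
to be conditionally independent given the state, so the joint likelihood is
a product and sequential updates commute.

`estimate_likelihoods()` derives these tables from a cohort: scores are cut
at pooled-quantile edges into 10 bins by default (deciles), conditional
frequencies are tallied per state with add-one smoothing, and both columns
renormalized. The source data's result alphabet is not documented, so the
bin count is a free parameter; deciles balance resolution against
estimation noise at a cohort size of order $10^4$, and the smoothing
prevents zero-likelihood results on finite cohorts.

## Strategy optimization

Ten strategies are compared (`strategies`): no treatment; treatment on
prior risk alone; each single test for an optimized segment; both test
orders with the second test optional after the first; and four
predetermined references (each test for all, TRS for all with GRS for
updated risks of 10–20\%, both for all). Each is solved by backward
induction (`solve_strategy()`): the treat decision first, then each
preceding test decision by taking the expectation of the continuation value
over the marginal result distribution, subtracting the test cost. Because
belief is the entire state, every decision rule is a function of current
risk alone.

Numerical choices:

* Posteriors inside the recursion are evaluated **exactly**; the 0–100\%
  integer grid is used only for reporting segments and for population
  weighting. Segment endpoints may therefore shift by up to one grid point
  relative to a formulation that rounds beliefs to the grid.
* Ties are broken in favour of fewer tests, then no treatment (strict
  inequality required to test or to treat), which minimizes intervention at
  equal NMB and makes output deterministic.
* The 10–20\% interval of the fixed TRS-then-GRS reference is closed at
  both ends.
* Fixed reference strategies still treat optimally at their terminal
  beliefs.
* In the sequential strategies, skipping the first test forecloses the
  second: the embedded fallback options are "no treatment" and "treatment
  on prior risk", not the other single-test strategy.

The dominance structure implied by nested policy spaces — the sequential
strategy weakly dominates its single-test restriction, which dominates
treatment-only, which dominates no-treatment; optimized segments dominate
test-everyone references — is asserted on random instances in the test
suite, and the dynamic program is checked against brute-force enumeration
of all deterministic policies on small instances (two tests, up to three
bins each, a few hundred policies).

`evaluate_strategy()` averages a solved policy over a population risk
distribution and propagates the mass through the branch probabilities to
obtain tested and treated shares; `rank_strategies()` produces the ranking
table.

## Sensitivity analyses

The probabilistic sensitivity analysis (`run_psa()`) re-draws six
parameters per trial — non-fatal event disutility ($-1\times$Beta(52,304)),
death probability (Beta(48,173)), statin risk reduction
($-1\times$Beta(45,121), applied as a relative reduction), GRS cost
(Unif(100,300)), and the two event costs (Gamma with shape 171 and scales
116 and 14) — re-derives the end states, re-solves every strategy, and
records the argmax per (WTP, trial) cell. Gammas are shape–scale so the
mean is $k\theta$; this is the only parameterization under which the
distribution means coincide with the base-case values and the 95\%
intervals with the stated ±15/25/50\% bands, which the tests verify
empirically. Parameters are drawn independently. Each (WTP, trial) cell has
its own substream seed derived from the master seed, so any single trial is
re-runnable in isolation. Shares are exact ratios of integer counts.

One-way analysis (`one_way_sensitivity()`) moves one parameter across its
band with full re-optimization and reports the NMB change of the sequential
optimized strategy. Two-way analysis (`two_way_sensitivity()`) maps the
(WTP, GRS-cost) region where that strategy attains the maximum NMB. Note a
subtlety: that region is *not* in general downward-closed in the GRS cost,
because cheaper genetic testing also helps the GRS-first competitors; the
monotone object is the strategy's advantage over its TRS-only restriction —
equivalently, whether GRS is part of the optimal testing strategy — and the
tests assert that form.

## The synthetic cohort

No subject-level data ships with the package. `generate_cohort()` draws the
latent event state Bernoulli(919/17,457 ≈ 5.3\%) across 17,457 subjects,
scores from state-conditional bivariate Gaussians whose mean separation is
set from target AUCs by the binormal identity
$\Delta\mu/\sigma = \sqrt{2}\,\Phi^{-1}(\mathrm{AUC})$, and fatality
Bernoulli(0.22) among events, independent of the scores. The default AUC
targets — TRS 0.80, GRS 0.65 — are fixture conventions of this package
(chosen as plausible for a multifactor clinical score and a polygenic score
respectively), not published quantities; every acceptance check that needs
fidelity to published numbers uses the printed parameters instead. The
default within-state score correlation is 0, matching the conditional
independence the Bayes engine assumes; the generator accepts any
correlation and the documented realistic ceiling is $|\rho| \le 0.09$.

`build_risk_distribution()` supplies the population weights over the
prior-risk grid: a Beta density discretized by CDF differencing over 101
equal-width cells (so the uniform Beta gives exactly 1/101 per grid point),
defaulting to a right-skewed Beta(2, 36) with mean at the population event
rate.

What the synthetic data do **not** emulate: the covariate structure behind
the real risk function (age, sex, blood pressure, cholesterol), any
non-Gaussian score shape, score-dependent fatality, and the actual
population risk distribution of the source registers. Consequently the
population-level magnitudes — ranking gaps, tested/treated shares, the
per-patient saving of including genetic testing — are qualitative on
synthetic data; what the package reproduces quantitatively is the economic
core (end-state valuation, weighted event costs, the treatment threshold)
plus every structural property of the optimizer.

## Problem sizes

The shipped analyses and tests run at desk scale as the package's own
reporting choice: likelihoods from a 17,457-subject synthetic cohort
(tests use a 6,000-subject fixture with 5 result bins), PSA at 200 trials
per WTP value on an 11-point WTP grid, calibration checks on cohorts of
40,000–60,000. Study-scale settings (1,000 trials, 51 WTP values, $10^5$
draws) are one argument away in `psa_config()` and the generator.

## Limitations

The model is static: it scores a single testing-and-treatment decision per
patient against a 10-year risk, without disease progression, re-testing, or
intervention timing (a Markov extension would be needed for those).
Treatment is statin therapy only, with full compliance. Test results carry
no health impact of their own, only costs. And the synthetic stand-ins above
mean population-level outputs should be read as demonstrations of the
machinery, not as estimates for any real population.
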