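# chdstrat

Health-economic decision modelling for targeting **risk-score testing and
statin therapy** in the primary prevention of coronary heart disease (CHD).

The package is built for health economists and biostatisticians who want to
optimize — not just compare — population testing strategies. A patient's
10-year CHD risk is the model's entire state: binned results of a
traditional clinical risk score (TRS) and/or a polygenic genetic risk score
(GRS) update that risk by Bayes' rule, and statin treatment is started when
the updated risk clears a cost-effectiveness threshold. Strategies are
valued in net monetary benefit,

```
NMB = QALYs × λ − Costs        (λ = willingness to pay, €/QALY)
```

and each testing strategy is solved by backward induction over its decision
tree: the treat/no-treat decision first, at every risk level, then each
preceding test decision by taking expectations of the continuation value
over the marginal result distribution. Ten strategies are compared, from
"treat nobody" through optimally targeted single tests to sequential
TRS-then-GRS testing and fixed test-everyone references. Probabilistic,
one-way, and two-way sensitivity analyses re-optimize at every parameter
draw. A synthetic cohort generator (binormal scores with controlled AUC,
conditionally independent given the event state) makes the whole pipeline
runnable without access to register data.

## Worked example

Value the four end states of the decision tree at base case, find the
treatment threshold, and rank all ten strategies on a synthetic population:

```r
library(chdstrat)

params <- econ_params()
es <- endstate_values(params)
es
#>   state      cost    qaly    nmb
#> 1     I      0.00 7.70277 385139
#> 2    II  -1927.83 7.68571 382358
#> 3   III -14685.15 6.94694 332662
#> 4    IV -12100.63 7.13880 344839

treatment_threshold(es)
#> [1] 0.1859056
```

State II (no event, treated) costs 1,928 € — ten discounted years of statin
plus monitoring — and loses 0.017 QALYs to statin side effects relative to
state I. State III (event, untreated) mixes fatal and non-fatal event paths
and loses 0.76 QALYs and 14,685 €. Treating is worthwhile once a patient's
10-year risk exceeds ~18.6%.

```r
cohort <- generate_cohort(cohort_spec(seed = 1))   # 17,457 subjects, ~919 events
lik_trs <- estimate_likelihoods(cohort, "trs")
lik_grs <- estimate_likelihoods(cohort, "grs")
dist <- build_risk_distribution()                  # right-skewed, mean ~5.3%

head(compare_strategies(es, lik_trs, lik_grs, dist), 3)
#>   strategy_id               label      nmb     cost    qaly share_trs share_grs share_treated
#> 5           v TRS & GRS optimized 382652.4 754.9461 7.66815  0.197567 0.0168950     0.0311081
#> 3         iii       TRS optimized 382650.7 751.8030 7.66805  0.197567 0.0000000     0.0299207
#> 6          vi GRS & TRS optimized 382630.6 749.2504 7.66760  0.086445 0.1070674     0.0206040
```

Sequential TRS-then-GRS testing ranks first: about 20% of the population is
worth testing with TRS, and GRS is added for the ~1.7% whose updated risk
remains too ambiguous to settle the treatment decision — the same
qualitative picture as targeting genetic testing at patients about whom
traditional risk factors are least informative.

## Analysis workflow

The `analysis/` scripts reproduce each stage end to end and write their
tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R   # synthetic cohort + likelihood tables
Rscript analysis/02_base_case.R         # end states, strategy ranking, policy segments
Rscript analysis/03_psa.R               # probabilistic sensitivity analysis
Rscript analysis/04_oneway_twoway.R     # one-way bands and the (WTP, GRS-cost) grid
```

All inputs come from `inst/extdata/base_case.yaml`; see
`vignettes/decision-model.Rmd` for the model's assumptions, conventions,
and limitations.

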