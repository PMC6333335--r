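# Base-case analysis configuration: economic parameters (2015 Euros),
# synthetic-cohort likelihood source, and population risk distribution.
seed: 1

economic_parameters:
  horizon_years: 10
  discount_rate: 0.03
  wtp: 50000
  qol_chd_free: 0.903          # weighted average of the age-band QoL table
  disutility_event: 0.147      # QALY loss of a non-fatal event, 1 year
  p_death_given_event: 0.22
  t_event: 5.75                # expected event time in years
  statin_relative_risk_reduction: 0.27
  statin_annual_disutility: 0.002
  cost_trs: 173
  cost_grs: 200
  cost_statin_annual: 53
  cost_monitoring_annual: 173
  cost_secondary_annual: 451
  # cost_nonfatal_event omitted: derived from event_costs (≈ 19,860)
  cost_fatal_event: 2417

event_costs:
  - {category: MI,          acute_cost: 8585,  followup_cost: 9814,  n_events: 11406}
  - {category: unstable_AP, acute_cost: 6702,  followup_cost: 10147, n_events: 2689}
  - {category: CABG,        acute_cost: 19483, followup_cost: 23666, n_events: 2493}
  - {category: PTCA,        acute_cost: 7122,  followup_cost: 8523,  n_events: 7901}

qol_by_age:
  - {age_band: 45-54, qol_chd_free: 0.935, disutility_event: -0.177}
  - {age_band: 55-64, qol_chd_free: 0.920, disutility_event: -0.177}
  - {age_band: 65-74, qol_chd_free: 0.900, disutility_event: -0.144}
  - {age_band: 75-84, qol_chd_free: 0.835, disutility_event: -0.085}
  - {age_band: "85+", qol_chd_free: null,  disutility_event: -0.012}

cohort:
  n_subjects: 17457
  event_rate: 0.05264938
  trs_auc: 0.80
  grs_auc: 0.65
  within_state_score_correlation: 0
  p_fatal: 0.22
  seed: 1
  n_bins: 10

risk_distribution:
  beta: {shape1: 2, shape2: 35.99}   # right-skewed, mean ~= 5.3% event rate
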