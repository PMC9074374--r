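# Model configuration: locally recurrent rectal cancer (LRRC).
# All monetary values in euros (plain decimals), probabilities per 3-month
# cycle unless stated otherwise, rates as annual fractions.
indication: LRRC
cycle_length: 0.25
horizon_cycles: 12
discount_rate_costs: 0.04
discount_rate_effects: 0.015
wtp: 80000
annual_incidence: 250
voi_horizon_years: 10
voi_discount_rate: 0.04
margin_r0:
  navigated: {family: beta, mean: 0.79, se: 0.0911}
  standard: {family: beta, mean: 0.49, se: 0.0771}
transitions:
  df_to_pd:
    R0:
      year1: {family: beta, mean: 0.159, se: 0.0798}
      year2: {family: beta, mean: 0.100, se: 0.0656}
      year3: {family: beta, mean: 0.100, se: 0.0656}
    R1:
      year1: {family: beta, mean: 0.252, se: 0.0926}
      year2: {family: beta, mean: 0.159, se: 0.0780}
      year3: {family: beta, mean: 0.159, se: 0.0780}
  pd_to_death:
    entry_year1: {family: beta, mean: 0.135, se: 0.0745}
    entry_year23: {family: beta, mean: 0.089, se: 0.1007}
  df_to_death: {family: fixed, mean: 0.0044, se: 0}
costs:
  surgery: {family: gamma, mean: 10970, se: 1399}
  navigation_addition: {family: gamma, mean: 3388, se: 432}
  state_df_per_cycle: {family: gamma, mean: 492, se: 63}
  state_pd_per_cycle: {family: gamma, mean: 585, se: 75}
  transition_df_to_pd: {family: gamma, mean: 13107, se: 1672}
utilities:
  first_cycle: {family: beta, mean: 0.70, se: 0.029}
  disease_free: {family: beta, mean: 0.85, se: 0.022}
  progressive_disease: {family: beta, mean: 0.77, se: 0.050}
scenarios:
  hybrid_or:
    label: "Hybrid OR construction included"
    navigation_addition: {family: gamma, mean: 6363, se: 812}
  utilization_50:
    label: "Navigation system utilisation 50% instead of 12%"
    navigation_addition: {family: gamma, mean: 1670, se: 213}
  combined:
    label: "Hybrid OR construction and 50% utilisation"
    navigation_addition: {family: fixed, mean: 4644.28, se: 0}
# Observed event counts (retrospective control cohort; one double-surgery
# patient excluded from the progression risk sets, hence 40 rather than 41).
observed_counts:
  margin_r0_navigated: {events: 15, at_risk: 19}
  margin_r0_standard: {events: 20, at_risk: 41}
  progression_r0_year1: {events: 9, at_risk: 20, observation_time: 1}
  progression_r0_year23: {events: 4, at_risk: 20, observation_time: 2}
  progression_r1_year1: {events: 11, at_risk: 20, observation_time: 1}
  progression_r1_year23: {events: 3, at_risk: 20, observation_time: 2}
  death_after_progression_year1: {events: 13, at_risk: 20, observation_time: 2.5}
  death_after_progression_year23: {events: 3, at_risk: 7, observation_time: 1.5}
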