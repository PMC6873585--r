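settings:
  discount_rate: 0.035
  horizon_cycles: 49
  efficacy_years: 11.0
  lambda: 120000.0
  start_age: 50.0
parameters:
  tp_dfs_chf:
    mean: 0.0053
    se: 0.0024
    dist: beta
    role: transition_prob
  tp_dfs_rec:
    mean: 0.0294
    se: 0.0029
    dist: beta
    role: transition_prob
  tp_dfs_met:
    mean: 0.0785
    se: 0.014
    dist: beta
    role: transition_prob
  tp_dfs_death:
    mean: 0.002
    se: 0.0001
    dist: beta
    role: transition_prob
  tp_chf_rec:
    mean: 0.0294
    se: 0.0029
    dist: beta
    role: transition_prob
  tp_chf_met:
    mean: 0.0785
    se: 0.014
    dist: beta
    role: transition_prob
  tp_chf_death:
    mean: 0.15
    se: 0.0153
    dist: beta
    role: transition_prob
  tp_rec_met:
    mean: 0.0785
    se: 0.014
    dist: beta
    role: transition_prob
  tp_rec_death:
    mean: 0.295
    se: 0.2066
    dist: beta
    role: transition_prob
  tp_met_death:
    mean: 0.295
    se: 0.2066
    dist: beta
    role: transition_prob
  hr_dfs:
    mean: 0.65
    se: 0.0825
    dist: lognormal
    role: relative_effect
  hr_os:
    mean: 0.67
    se: 0.0493
    dist: lognormal
    role: relative_effect
  rr_chf:
    mean: 3.97
    se: 0.224
    dist: lognormal
    role: relative_effect
  u_dfs:
    mean: 0.832
    se: 0.0084
    dist: beta
    role: utility
  u_chf:
    mean: 0.67
    se: 0.0262
    dist: beta
    role: utility
  u_rec:
    mean: 0.828
    se: 0.0262
    dist: beta
    role: utility
  u_met:
    mean: 0.762
    se: 0.0262
    dist: beta
    role: utility
  dmc_tx_trast:
    mean: 1076607.0
    se: 54929.0
    dist: gamma
    role: cost_dmc
  dmc_tx_ct:
    mean: 194900.0
    se: 9944.0
    dist: gamma
    role: cost_dmc
  dnmc_tx_trast:
    mean: 9432.0
    se: 481.0
    dist: gamma
    role: cost_dnmc
  dnmc_tx_ct:
    mean: 3494.0
    se: 178.0
    dist: gamma
    role: cost_dnmc
  dmc_dfs:
    mean: 9493.0
    se: 484.0
    dist: gamma
    role: cost_dmc
  dnmc_dfs:
    mean: 1747.0
    se: 80.0
    dist: gamma
    role: cost_dnmc
  dmc_chf:
    mean: 3400.0
    se: 1602.0
    dist: gamma
    role: cost_dmc
  dnmc_chf:
    mean: 1049.0
    se: 52.0
    dist: gamma
    role: cost_dnmc
  dmc_rec_y1:
    mean: 567156.0
    se: 3061.0
    dist: gamma
    role: cost_dmc
  dnmc_rec_y1:
    mean: 8166.0
    se: 1488.0
    dist: gamma
    role: cost_dnmc
  dmc_rec_later:
    mean: 182437.0
    se: 15513.0
    dist: gamma
    role: cost_dmc
  dnmc_rec_later:
    mean: 17817.0
    se: 178.0
    dist: gamma
    role: cost_dnmc
  dmc_rec_later_alt:
    mean: 516904.0
    se: 26373.0
    dist: gamma
    role: cost_dmc
  dnmc_rec_later_alt:
    mean: 5939.0
    se: 273.0
    dist: gamma
    role: cost_dnmc
  dmc_met_y1:
    mean: 956172.0
    se: 48784.0
    dist: gamma
    role: cost_dmc
  dnmc_met_y1:
    mean: 10131.0
    se: 465.0
    dist: gamma
    role: cost_dnmc
  dmc_met_later:
    mean: 1666816.0
    se: 59531.0
    dist: gamma
    role: cost_dmc
  dnmc_met_later:
    mean: 5939.0
    se: 273.0
    dist: gamma
    role: cost_dnmc
  trast_drug_cost_per_course:
    mean: 619667.0
    se: 0.0
    dist: fixed
    role: cost_dmc
  prevalent_bc:
    mean: 64046.0
    se: 0.0
    dist: fixed
    role: epidemiology
  incident_bc:
    mean: 21057.0
    se: 0.0
    dist: fixed
    role: epidemiology
  her2_rate:
    mean: 0.2317
    se: 0.0
    dist: fixed
    role: epidemiology
  early_rate:
    mean: 0.8
    se: 0.0
    dist: fixed
    role: epidemiology
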