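seed: 20231
model:
  horizon: 26
  cohort_size: 10000
  include_development: yes
  visit_multiplier: yes
  psa_outer: 1000
  psa_inner: 1000
  psa_inner_microsim: no
  wtp:
    from: 0.0
    to: 20000.0
    by: 250.0
costs:
  c_ed_visit: 1135.0
  c_ed_visit_sd: 33.0
  c_night: 3574.0
  c_night_sd: 122.0
  dev_total: 491118.0
  dev_per_patient: 1253.0
  np_wage: 59.8
  np_hours_dss: 19.79
  np_hours_nondss: 11.46
  intervention_cost_per_patient:
    SCC: 1253.0
    SCC_AT: 1253.0
    NP: 1309.0
    NP_DSS: 1343.0
    COMPLETE_SCH: 1340.0
arms:
- arm: SCC
  n_patients: 143
  p_ed: 0.037
  p_ed_sd: 0.079
  n_ed: 1.6
  n_ed_sd: 0.8
  p_hosp: 0.034
  p_hosp_sd: 0.089
  n_hosp: 1.3
  n_hosp_sd: 0.4
  los: 4.7
  los_sd: 4.2
  burden:
    a: 6.396
    b: 0.06
    c: -0.003
  adherence:
    alpha: 0.2
    beta: 0.1474
  dropout:
    mean: 69.6
    sd: 25.6
    cap: 182.0
- arm: SCC_AT
  n_patients: 147
  p_ed: 0.042
  p_ed_sd: 0.108
  n_ed: 2.0
  n_ed_sd: 1.8
  p_hosp: 0.025
  p_hosp_sd: 0.069
  n_hosp: 1.3
  n_hosp_sd: 0.7
  los: 5.0
  los_sd: 4.6
  burden:
    a: 6.796
    b: 0.06
    c: -0.003
  adherence:
    alpha: 0.2
    beta: 0.1474
  dropout:
    mean: 69.6
    sd: 25.6
    cap: 182.0
- arm: NP
  n_patients: 150
  p_ed: 0.044
  p_ed_sd: 0.098
  n_ed: 1.7
  n_ed_sd: 1.0
  p_hosp: 0.03
  p_hosp_sd: 0.094
  n_hosp: 1.4
  n_hosp_sd: 0.6
  los: 5.2
  los_sd: 3.4
  burden:
    a: 5.096
    b: 0.06
    c: -0.003
  adherence:
    alpha: 0.2
    beta: 0.1474
  dropout:
    mean: 69.6
    sd: 25.6
    cap: 182.0
- arm: NP_DSS
  n_patients: 157
  p_ed: 0.031
  p_ed_sd: 0.066
  n_ed: 2.1
  n_ed_sd: 2.9
  p_hosp: 0.02
  p_hosp_sd: 0.053
  n_hosp: 1.7
  n_hosp_sd: 1.9
  los: 3.6
  los_sd: 2.2
  burden:
    a: 5.196
    b: 0.06
    c: -0.003
  adherence:
    alpha: 0.2
    beta: 0.1474
  dropout:
    mean: 69.6
    sd: 25.6
    cap: 182.0
- arm: COMPLETE_SCH
  n_patients: 171
  p_ed: 0.047
  p_ed_sd: 0.144
  n_ed: 1.7
  n_ed_sd: 1.8
  p_hosp: 0.027
  p_hosp_sd: 0.085
  n_hosp: 1.3
  n_hosp_sd: 0.6
  los: 4.7
  los_sd: 4.4
  burden:
    a: 4.396
    b: 0.06
    c: -0.003
  adherence:
    alpha: 0.2
    beta: 0.1474
  dropout:
    mean: 69.6
    sd: 25.6
    cap: 182.0
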