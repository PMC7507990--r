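population: pdl1_ge50
settings:
  cycle_length_days: 42.0
  horizon_years: 20.0
  annual_discount_rate: 0.03
  wtp: 150000.0
  half_cycle_correction: no
  ae_accrual: per_cycle
  apply_discontinuation: no
  ct_interval_pfs_weeks: 6.0
  ct_interval_pd_weeks: 9.0
prices:
  nivolumab: 17517.150000000001
  ipilimumab: 10718.959999999999
  pemetrexed: 12782.85
  gemcitabine: 92.0
  carboplatin: 56.55
  cisplatin: 51.78
  pembrolizumab: 19755.599999999999
  radiotherapy: 15899.24
  targeted_therapy: 12615.68
  subsequent_chemotherapy: 238.74
ae_costs:
  rash: 13376.0
  diarrhea: 10301.0
  fatigue: 0.0
  decreased_appetite: 9711.0
  anemia: 7969.56
  neutropenia: 32995.0
  neutrophil_count_decreased: 32995.0
  nausea: 10301.0
  vomiting: 10301.0
other_costs:
  administration: 139.61
  ct_scan: 231.0
  laboratory: 315.0
utilities:
  pfs_intervention: 0.784
  pfs_comparator: 0.693
  pd: 0.473
reference_patient:
  age_years: 65.0
  weight_kg: 70.0
  height_cm: 178.0
  bsa_m2: 1.84
  target_auc: 6.0
  serum_creatinine: 1.0
intervention:
  name: nivolumab plus ipilimumab
  pfs:
    shape: 0.53605
    scale: 0.27369
  os:
    shape: 0.658678
    scale: 0.112585
  treatment:
    type: components
    components:
    - nivolumab
    - ipilimumab
    max_cycles: 22.0
  discontinuation: 0.422
  ae:
  - name: rash
    risk: 0.023
  - name: diarrhea
    risk: 0.015
  - name: fatigue
    risk: 0.02
  - name: decreased_appetite
    risk: 0.01
  - name: anemia
    risk: 0.013
  subsequent:
  - therapy: radiotherapy
    proportion: 0.174
    accrual: per_cycle
  - therapy: subsequent_chemotherapy
    proportion: 0.316
    accrual: per_cycle
  - therapy: nivolumab
    proportion: 0.04
    accrual: per_cycle
  - therapy: targeted_therapy
    proportion: 0.053
    accrual: per_cycle
comparator:
  name: platinum-doublet chemotherapy
  pfs:
    shape: 1.10045
    scale: 0.17421
  os:
    shape: 0.868245
    scale: 0.093252
  treatment:
    type: doublet
    nonsquamous: 0.708
    carboplatin_share: 0.5
    induction_cycles: 2.0
    maintenance: pemetrexed
  discontinuation: 0.625
  ae:
  - name: anemia
    risk: 0.106
  - name: neutropenia
    risk: 0.07
  - name: neutrophil_count_decreased
    risk: 0.085
  - name: nausea
    risk: 0.018
  - name: fatigue
    risk: 0.01
  - name: decreased_appetite
    risk: 0.01
  - name: vomiting
    risk: 0.026
  subsequent:
  - therapy: radiotherapy
    proportion: 0.244
    accrual: per_cycle
  - therapy: subsequent_chemotherapy
    proportion: 0.275
    accrual: per_cycle
  - therapy: nivolumab
    proportion: 0.325
    accrual: per_cycle
  - therapy: pembrolizumab
    proportion: 0.081
    accrual: per_cycle
  - therapy: targeted_therapy
    proportion: 0.043
    accrual: per_cycle
sa_ranges:
- path: utilities.pfs_intervention
  min: 0.74
  max: 0.828
  dist: beta
- path: utilities.pfs_comparator
  min: 0.642
  max: 0.743
  dist: beta
- path: utilities.pd
  min: 0.166
  max: 0.568
  dist: beta
- path: intervention.ae.rash
  min: 0.0184
  max: 0.0276
  dist: beta
- path: intervention.ae.diarrhea
  min: 0.012
  max: 0.018
  dist: beta
- path: intervention.ae.fatigue
  min: 0.016
  max: 0.024
  dist: beta
- path: intervention.ae.decreased_appetite
  min: 0.008
  max: 0.012
  dist: beta
- path: intervention.ae.anemia
  min: 0.0104
  max: 0.0156
  dist: beta
- path: comparator.ae.anemia
  min: 0.0848
  max: 0.1272
  dist: beta
- path: comparator.ae.neutropenia
  min: 0.056
  max: 0.084
  dist: beta
- path: comparator.ae.neutrophil_count_decreased
  min: 0.068
  max: 0.102
  dist: beta
- path: comparator.ae.nausea
  min: 0.0144
  max: 0.0216
  dist: beta
- path: comparator.ae.fatigue
  min: 0.008
  max: 0.012
  dist: beta
- path: comparator.ae.decreased_appetite
  min: 0.008
  max: 0.012
  dist: beta
- path: comparator.ae.vomiting
  min: 0.0208
  max: 0.0312
  dist: beta
- path: prices.nivolumab
  min: 14013.719999999999
  max: 21020.580000000002
  dist: gamma
- path: prices.ipilimumab
  min: 8575.17
  max: 12862.75
  dist: gamma
- path: prices.pemetrexed
  min: 10226.280000000001
  max: 15339.42
  dist: gamma
- path: prices.gemcitabine
  min: 73.6
  max: 110.4
  dist: gamma
- path: prices.carboplatin
  min: 45.24
  max: 67.86
  dist: gamma
- path: prices.cisplatin
  min: 41.42
  max: 62.14
  dist: gamma
- path: prices.pembrolizumab
  min: 15804.48
  max: 23706.720000000001
  dist: gamma
- path: prices.radiotherapy
  min: 12719.389999999999
  max: 19079.09
  dist: gamma
- path: prices.targeted_therapy
  min: 10092.540000000001
  max: 15138.82
  dist: gamma
- path: prices.subsequent_chemotherapy
  min: 190.99
  max: 286.49
  dist: gamma
- path: ae_costs.rash
  min: 10700.799999999999
  max: 16051.200000000001
  dist: gamma
- path: ae_costs.diarrhea
  min: 8240.799999999999
  max: 12361.200000000001
  dist: gamma
- path: ae_costs.decreased_appetite
  min: 7768.8
  max: 11653.200000000001
  dist: gamma
- path: ae_costs.anemia
  min: 6375.65
  max: 9536.469999999999
  dist: gamma
- path: ae_costs.neutropenia
  min: 24746.0
  max: 41244.0
  dist: gamma
- path: ae_costs.neutrophil_count_decreased
  min: 24746.0
  max: 41244.0
  dist: gamma
- path: ae_costs.nausea
  min: 8240.799999999999
  max: 12361.200000000001
  dist: gamma
- path: ae_costs.vomiting
  min: 8240.799999999999
  max: 12361.200000000001
  dist: gamma
- path: other_costs.administration
  min: 111.69
  max: 167.53
  dist: gamma
- path: other_costs.ct_scan
  min: 208.0
  max: 254.0
  dist: gamma
- path: other_costs.laboratory
  min: 252.0
  max: 378.0
  dist: gamma
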