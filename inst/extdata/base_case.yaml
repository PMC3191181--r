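prev_normo: 0.79
prev_micro: 0.18
prev_macro: 0.03
q_nm: 0.056
q_mM: 0.094
q_ME: 0.056
rr_nm: 0.6
rr_mM: 0.45
rr_ME: 0.61
smr: 1.41
q_esrd_death: 0.09
u_diabetes: 0.88
u_esrd: 0.62
u_treat_mult: 1.0
c_drug_mixed: 62.700000000000003
c_ace: 6.96
c_arb: 298.680000000000007
arb_rate: 0.099
c_screen_micro: 7.0
c_screen_macro: 1.12
esrd_costs:
  beta1: 0.82
  beta2: 0.106
  beta3: 0.074
  x1: 83217.0
  x2: 54067.0
  x3: 69546.0
  p: 0.43
  'y': 14387.0
c_esrd_override: 42110.0
c_diabetes_excess: 547.0
exp_lo: 3310.230000000000018
exp_hi: 23626.229999999999563
esrd_cost_replaces_background: no
age_entry: 50.0
age_end: 99.0
r_cost: 0.04
r_effect: 0.015
spec_micro: 1.0
cohort_size: 1000.0
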