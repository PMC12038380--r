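# Demonstration simulation configuration: a small synthetic cohort with the
# default generative hazard ratios. Any field of sim_config() may be set here;
# omitted fields keep their defaults.
n_patients: 500
horizon_days: 1095
baseline_intensity: 0.001
factor_prevalences:
  inpatient: 0.18
  black: 0.18
  female: 0.07
censor_rates:
  new_indication: 0.05
  gi_bleed: 0.02
hp_positive_fraction: 0.05
ineligible_fraction: 0.1
seed: 20
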