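# Default cohort-simulation settings for `bprs simulate --config`.
# Any field named like a cohortConfig() argument overrides the packaged
# default; effect sizes and prevalences stay at the packaged values.
n_cases: 1248
n_controls: 400
dur_beta: 0.02
age_beta: 0.01
baseline_hazard: 0.02
censor_rate: 0.04
max_followup: 40
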