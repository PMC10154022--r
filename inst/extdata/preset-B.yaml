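label: preset-B
description: >
  Synthetic natural-history parameterization B. Lognormal frailty with a
  flatter onset hazard, slower lognormal diameter growth, exponential
  preclinical sojourn (mean 5 years), per-lesion FIT positivity with an
  early/late preclinical-stage split at the sojourn midpoint. Not a
  calibrated registry model.
adenoma_onset:
  age_breaks: [0.0, 20.0, 30.0, 40.0, 50.0, 60.0, 70.0, 100.0]
  base_hazard: [0.0, 0.002, 0.005, 0.010, 0.016, 0.024, 0.030]
  frailty_dist: lognormal
  frailty_var: 1.8
  max_lesions: 60
growth:
  rate_meanlog: -2.30
  rate_sdlog: 0.65
  reach_prob: 1.0
transformation:
  small: 0.0001
  medium: 0.002
  large: 0.018
sojourn:
  dist: exponential
  mean: 5.0
crc_survival:
  clin_meanlog: 1.6094
  screen_meanlog: 2.6391
  sdlog: 1.25
fit:
  mode: per_lesion
  sens:
    small: 0.00
    medium: 0.114
    large: 0.159
  sens_preclinical: [0.62565, 0.886]
  specificity: 0.97
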