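label: preset-A
description: >
  Synthetic natural-history parameterization A. Gamma frailty on a
  piecewise-constant adenoma onset hazard, lognormal diameter growth,
  lognormal preclinical sojourn (mean about 3.5 years), per-person FIT
  positivity. Not a calibrated registry model.
adenoma_onset:
  age_breaks: [0.0, 20.0, 30.0, 40.0, 50.0, 60.0, 70.0, 100.0]
  base_hazard: [0.0, 0.0015, 0.004, 0.009, 0.018, 0.028, 0.034]
  frailty_dist: gamma
  frailty_var: 1.2
  max_lesions: 60
growth:
  rate_meanlog: -2.16
  rate_sdlog: 0.55
  reach_prob: 1.0
transformation:
  small: 0.0002
  medium: 0.0015
  large: 0.015
sojourn:
  dist: lognormal
  meanlog: 1.0986
  sdlog: 0.55
crc_survival:
  clin_meanlog: 1.7918
  screen_meanlog: 2.7726
  sdlog: 1.3
fit:
  mode: per_person
  sens:
    small: 0.05
    medium: 0.15
    large: 0.22
  sens_preclinical: [0.74, 0.74]
  specificity: 0.97
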