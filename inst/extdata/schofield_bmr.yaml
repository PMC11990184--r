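# Adult BMR prediction coefficients (MJ/day = slope x weight_kg + intercept),
# Schofield-type, one record per sex and age band; the youngest adult band
# includes age 30 and the middle band includes age 60.
- sex: male
  age_min: 18
  age_max: 30
  slope: 0.063
  intercept: 2.896
- sex: male
  age_min: 30
  age_max: 60
  slope: 0.048
  intercept: 3.653
- sex: male
  age_min: 60
  age_max: 120
  slope: 0.049
  intercept: 2.459
- sex: female
  age_min: 18
  age_max: 30
  slope: 0.062
  intercept: 2.036
- sex: female
  age_min: 30
  age_max: 60
  slope: 0.034
  intercept: 3.538
- sex: female
  age_min: 60
  age_max: 120
  slope: 0.038
  intercept: 2.755
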