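# SYNTHETIC coefficient/calibration configuration for the SCORE2-style
# linear predictor. These values are NOT the published SCORE2 coefficients
# and must not be used clinically: they are structural placeholders that
# satisfy the monotonicity and calibration-shape properties of the
# published formula, for use with synthetic cohorts. Replace this file
# with a licensed coefficient set to score real data.
name: score2-synthetic
terms:
  - variable: age
    center: 60
    scale: 5
    coefficient: 0.35
  - variable: sbp
    center: 120
    scale: 20
    coefficient: 0.30
  - variable: ldl_c
    center: 3.6
    scale: 1.0
    coefficient: 0.25
  - variable: smoking
    coefficient: 0.50
  - variable: diabetes
    coefficient: 0.60
  - variable: sex
    coefficient: 0.40
calibration:
  baseline_survival: 0.95
  scale1: -0.10
  scale2: 1.00
  horizon: 3
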