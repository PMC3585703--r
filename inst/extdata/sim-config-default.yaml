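# Default simulation configuration (schema gestage-sim-config-v1).
# Availability rates follow a public-sector antenatal cohort; error
# magnitudes are field-realistic choices documented in the methods vignette.
schema: gestage-sim-config-v1
"n": 1483   # quoted: bare n is a YAML 1.1 boolean
start_date: "2008-01-01"
birth_span_days: 365
sex_male_p: 0.512
true_ga:
  # three-component truncated-normal mixture over GA at birth (days)
  p_preterm: 0.125
  p_term: 0.855
  p_postterm: 0.020
  preterm: {mean: 245, sd: 14, min: 154, max: 258}
  term: {mean: 277, sd: 8, min: 259, max: 293}
  postterm: {mean: 297, sd: 3, min: 294, max: 315}
lmp:
  available_p: 0.974
  certain_p: 0.769          # conditional on LMP being available
  sd_sure_days: 8
  sd_unsure_days: 16
  month_slip_p: 0.25        # uncertain dates only
  month_slip_later_p: 0.8   # recall slips mostly toward the missed period
us:
  window_p: [0.786, 0.598, 0.617]   # 7-20w, 21-28w, 29+w availability
  error_sd_days: [4, 8, 14]
capurro:
  available_p: 0.875
  shrink: 0.15              # pull of the exam estimate toward term
  target_days: 273
  noise_sd_days: 5
weight:
  noise_sd_multiplier: 1.0  # x reference SD at the true GA week
  gross_error_p: 0.01       # transcription-style gross errors
  gross_min_g: 500
  gross_max_g: 6000
covariates:
  city: {city1: 0.58, city2: 0.42}
  age_group: {"10-19": 0.22, "20-34": 0.693, ">=35": 0.087}
  ethnicity: {white: 0.36, mixed: 0.42, black: 0.22}
  schooling: {"<=4": 0.125, "5-8": 0.44, ">=9": 0.435}
  marital: {married: 0.75, not_married: 0.25}
  parity: {"1": 0.45, "2-3": 0.425, ">=4": 0.125}
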