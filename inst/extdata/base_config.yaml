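# Base-case run configuration: synthetic survival inputs calibrated to the
# CheckMate 901 printed medians/CIs, base-case economics, all analyses on.
seed: 20240901
synthetic:
  use: true
  n0: 300              # cohort size behind each emulated digitized curve
  n_ref: 300           # reference arm size for shape calibration
  risk_interval: 3     # months between numbers-at-risk entries
  read_interval: 1     # months between curve read-off points
  jitter_sd: 0.002     # digitization error, survival units
  censor_rate: 0.1
  max_follow_up: 36    # months
life_table: null       # null -> synthetic Gompertz-Makeham table
model:
  start_age: 65
  horizon_years: 10
  cycle_length_weeks: 1
  discount_annual: 0.05
  wtp: 38223
  weight_kg: 65
  height_m: 1.65
  second_line_blocks: 6
  wastage: whole_vial
analyses:
  base: true
  owsa: true
  psa: true
  threshold: true
  psa_n: 5000
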