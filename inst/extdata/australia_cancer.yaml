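# Whole-grain cost-of-illness analysis: Australian adults (>= 20 years).
# Pooled dose-response RRs per 90 g/day of whole-grain food; AIHW direct
# health expenditure (AUD million), 2015-16 base year and 2020 prices.
# The pipeline uses the current-year (2020) expenditure columns directly.
intakes:
  current: 21          # median adult whole-grain intake, g/day content
  target: 48           # daily target intake, g/day content
  product_to_content_ratio: 1.875   # 30 g product carries 16 g content
outcomes:
  - condition: colorectal cancer
    outcome: colorectal cancer
    rr: 0.83
    ci_lower: 0.78
    ci_upper: 0.89
    dose_g: 90
    n_studies: 6
    expenditure: crc_expenditure_2020.csv
    year: 2020
    expenditure_base: crc_expenditure_2015-16.csv
    base_year: "2015-16"
    report_digits: 2
  - condition: total cancers
    outcome: total cancer mortality
    rr: 0.85
    ci_lower: 0.80
    ci_upper: 0.91
    dose_g: 90
    n_studies: 6
    expenditure: total_cancers_expenditure_2020.csv
    year: 2020
    expenditure_base: total_cancers_expenditure_2015-16.csv
    base_year: "2015-16"
    report_digits: 1
scenarios:
  block_length: 5
  horizon: 20
  blocks:
    - name: very pessimistic
      uptake: 0.05
    - name: pessimistic
      uptake: 0.15
    - name: optimistic
      uptake: 0.50
    - name: universal
      uptake: 1.00
discount:
  rate: 0.07
options:
  scaling: linear
  strict_content_units: false
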