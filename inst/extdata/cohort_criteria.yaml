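delivery_window:
- '2017-01-01'
- '2020-12-31'
prenatal_codes:
- Z34
- O09
delivery_codes:
- 10D0
- 10E0
age_min: 18
age_max: 35
excluded_visit_types:
- portal message
- phone call
excluded_registration_years: 1900
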