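- factor_id: dyspnea
  description: Dyspnea
  kind: symptom
  persistence: variable
  trigger: presence
  red_flag_on_presence: yes
  labels:
  - dyspnea
  - shortness of breath
- factor_id: orthopnea
  description: Orthopnea
  kind: symptom
  persistence: variable
  trigger: presence
  red_flag_on_presence: yes
  labels:
  - orthopnea
- factor_id: tachypnea_symptom
  description: Tachypnea (coded symptom)
  kind: symptom
  persistence: variable
  trigger: presence
  red_flag_on_presence: no
  labels:
  - tachypnea
- factor_id: asthma_unresponsive
  description: Asthma unresponsive to therapy
  kind: symptom
  persistence: variable
  trigger: presence
  red_flag_on_presence: no
  labels:
  - asthma unresponsive to therapy
- factor_id: swelling_face_hands
  description: Swelling in face or hands
  kind: symptom
  persistence: variable
  trigger: presence
  red_flag_on_presence: no
  labels:
  - swelling in face or hands
  - facial swelling
- factor_id: new_worsening_headache
  description: New or worsening headache
  kind: symptom
  persistence: variable
  trigger: presence
  red_flag_on_presence: no
  labels:
  - new or worsening headache
- factor_id: palpitations
  description: Heart palpitations
  kind: symptom
  persistence: variable
  trigger: presence
  red_flag_on_presence: no
  labels:
  - heart palpitations
  - palpitations
- factor_id: dizziness_syncope
  description: Dizziness or syncope
  kind: symptom
  persistence: variable
  trigger: presence
  red_flag_on_presence: no
  labels:
  - dizziness
  - syncope
- factor_id: chest_pain
  description: Chest pain
  kind: symptom
  persistence: variable
  trigger: presence
  red_flag_on_presence: no
  labels:
  - chest pain
- factor_id: loud_heart_murmur
  description: Loud heart murmur
  kind: physical_finding
  persistence: variable
  trigger: presence
  red_flag_on_presence: no
  labels:
  - loud heart murmur
- factor_id: basilar_crackles
  description: Basilar crackles in lungs
  kind: physical_finding
  persistence: variable
  trigger: presence
  red_flag_on_presence: no
  labels:
  - basilar crackles
  - basilar crackles in lungs
- factor_id: heart_rate_high
  description: Resting heart rate >= 110 bpm (red flag >= 120)
  kind: physical_finding
  persistence: variable
  trigger: numeric
  quantity: heart_rate
  direction: ge
  threshold_standard: 110.0
  threshold_red: 120.0
  red_flag_on_presence: no
  labels:
  - heart rate
  - resting heart rate
  - pulse rate
- factor_id: sbp_high
  description: Systolic blood pressure >= 140 mm Hg (red flag >= 160)
  kind: physical_finding
  persistence: variable
  trigger: numeric
  quantity: systolic_bp
  direction: ge
  threshold_standard: 140.0
  threshold_red: 160.0
  red_flag_on_presence: no
  labels:
  - systolic blood pressure
  - sbp
- factor_id: resp_rate_high
  description: Respiratory rate >= 24 /min (red flag >= 30)
  kind: physical_finding
  persistence: variable
  trigger: numeric
  quantity: resp_rate
  direction: ge
  threshold_standard: 24.0
  threshold_red: 30.0
  red_flag_on_presence: no
  labels:
  - respiratory rate
  - resp rate
- factor_id: spo2_low
  description: Oxygen saturation <= 96% (red flag <= 94%)
  kind: physical_finding
  persistence: variable
  trigger: numeric
  quantity: spo2
  direction: le
  threshold_standard: 96.0
  threshold_red: 94.0
  red_flag_on_presence: no
  labels:
  - oxygen saturation
  - spo2
  - pulse oximetry
- factor_id: age_40
  description: Aged >= 40 years
  kind: history
  persistence: static
  trigger: numeric
  quantity: age
  direction: ge
  threshold_standard: 40.0
  red_flag_on_presence: no
  labels:
  - age
- factor_id: race_african_american
  description: 'Race: African American'
  kind: history
  persistence: static
  trigger: presence
  red_flag_on_presence: no
  labels:
  - african american
- factor_id: prepregnancy_obesity
  description: Prepregnancy obesity (BMI >= 35)
  kind: history
  persistence: static
  trigger: numeric
  quantity: bmi
  direction: ge
  threshold_standard: 35.0
  red_flag_on_presence: no
  labels:
  - prepregnancy bmi
  - pre-pregnancy bmi
- factor_id: prepregnancy_diabetes
  description: Prepregnancy diagnosis of diabetes
  kind: history
  persistence: static
  trigger: presence
  red_flag_on_presence: no
  labels:
  - prepregnancy diabetes
  - pregestational diabetes
- factor_id: prepregnancy_hypertension
  description: Prepregnancy diagnosis of hypertension
  kind: history
  persistence: static
  trigger: presence
  red_flag_on_presence: no
  labels:
  - prepregnancy hypertension
  - chronic hypertension
- factor_id: substance_use
  description: Substance use (nicotine, cocaine, alcohol, methamphetamines)
  kind: history
  persistence: static
  trigger: presence
  red_flag_on_presence: no
  labels:
  - history of substance use
  - substance use
- factor_id: history_chemotherapy
  description: History of chemotherapy
  kind: history
  persistence: static
  trigger: presence
  red_flag_on_presence: no
  labels:
  - history of chemotherapy
- factor_id: history_labor_complications
  description: History of complications in labor or delivery
  kind: history
  persistence: static
  trigger: presence
  red_flag_on_presence: no
  labels:
  - history of labor or delivery complications
  - history of complications in labor or delivery
- factor_id: history_heart_disease
  description: History of heart disease
  kind: history
  persistence: static
  trigger: presence
  red_flag_on_presence: no
  labels:
  - history of heart disease
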