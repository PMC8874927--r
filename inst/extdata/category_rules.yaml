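- target: event
  field: event_label
  pattern: ^(systolic blood pressure|heart rate|respiratory rate|oxygen saturation)$
  category: event
  sub_category: measurements
  clinical_cat: vitals
- target: event
  field: event_label
  pattern: ^(weight|prepregnancy bmi)$
  category: event
  sub_category: measurements
  clinical_cat: weight and BMI
- target: event
  field: event_label
  pattern: ^(hemoglobin|platelet count)$
  category: event
  sub_category: labs
  clinical_cat: hematology
- target: event
  field: event_label
  pattern: ^(glucose|creatinine|alt|ast)$
  category: event
  sub_category: labs
  clinical_cat: metabolic panel
- target: event
  field: event_label
  pattern: ^(dyspnea|shortness of breath|orthopnea|tachypnea|chest pain|heart palpitations|palpitations|dizziness|syncope|new
    or worsening headache|swelling in face or hands|facial swelling|asthma unresponsive
    to therapy|nausea of pregnancy)$
  category: event
  sub_category: symptoms
- target: event
  field: event_label
  pattern: ^(loud heart murmur|basilar crackles)
  category: event
  sub_category: physical findings
- target: event
  field: event_label
  pattern: ^(history of|prepregnancy )
  category: event
  sub_category: history
- target: diagnosis
  field: diagnosis_type
  pattern: ^admitting diagnosis$
  category: diagnosis
  sub_category: admitting diagnosis
- target: diagnosis
  field: diagnosis_type
  pattern: ^discharge diagnosis$
  category: diagnosis
  sub_category: discharge diagnosis
- target: diagnosis
  field: diagnosis_type
  pattern: ^encounter diagnosis$
  category: diagnosis
  sub_category: encounter diagnosis
- target: diagnosis
  field: diagnosis_type
  pattern: ^procedure$
  category: diagnosis
  sub_category: procedure
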