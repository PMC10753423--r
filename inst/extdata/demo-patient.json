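{
  "patient_id": "demo_patient",
  "values": {
    "cigarettes_per_day": 0,
    "fev1_pct_predicted": 95,
    "hospitalizations_past_year": false,
    "ics_dose": "low",
    "indoor_allergen_sensitization": true,
    "prescribed_medication": true,
    "secondhand_smoke_exposure": false,
    "self_reported_asthma": true
  }
}
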