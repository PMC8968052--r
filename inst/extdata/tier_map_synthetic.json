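{
  "comment": "Synthetic reconstruction of the clinical extraction-timeline tier map (the source figure is not redistributable); tiers follow variable availability: 0 patient baseline, 1 diagnostic staging, 2 neoadjuvant treatment, 3 surgery, 4 pathology/adjuvant, 5 follow-up outcome.",
  "tiers": {
    "age": 0,
    "gender": 0,
    "clinical_t": 1,
    "clinical_n": 1,
    "tumor_distance": 1,
    "neoadjuvant_chemo": 2,
    "rt_dose": 2,
    "overall_treatment_time": 2,
    "interval_rt_surgery": 2,
    "surgery_procedure": 3,
    "crm": 4,
    "pathological_t": 4,
    "pathological_n": 4,
    "adjuvant_chemo": 4,
    "outcome": 5
  }
}
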