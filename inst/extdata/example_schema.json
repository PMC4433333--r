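{
  "id_column": "patient_id",
  "outcome_column": "died30",
  "score_columns": ["saps"],
  "features": [
    {"name": "age", "kind": "continuous"},
    {"name": "hr_min", "kind": "continuous"},
    {"name": "hr_max", "kind": "continuous"},
    {"name": "gcs_min", "kind": "continuous"},
    {"name": "service", "kind": "categorical"},
    {"name": "vasopressor", "kind": "categorical"}
  ]
}
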