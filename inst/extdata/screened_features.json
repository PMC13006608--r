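{
  "comment": "Retained-feature lists from the two importance screens of the study's registry analysis (threshold 5%).",
  "rf": ["ast", "cholinesterase", "ais_weighted", "albumin", "other_dx_score", "primary_dx_score", "hb", "creatinine", "prealbumin", "ada"],
  "xgboost": ["albumin", "ada", "ast", "hb", "other_dx_score", "prealbumin", "heart_rate", "ais_weighted"]
}
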