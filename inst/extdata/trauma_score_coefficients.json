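{
  "rts": {
    "comment": "Revised Trauma Score: weighted sum of coded (0-4) GCS, systolic blood pressure and respiratory rate; standard published coefficients.",
    "gcs": 0.9368,
    "sbp": 0.7326,
    "rr": 0.2908
  },
  "triss": {
    "comment": "TRISS survival probability, blunt-trauma coefficient set (MTOS): logit = b0 + b1*RTS + b2*ISS + b3*AgeIndex; AgeIndex = 0 if age < 55 else 1.",
    "blunt": {"b0": -0.4499, "b1": 0.8085, "b2": -0.0835, "b3": -1.743},
    "penetrating": {"b0": -2.5355, "b1": 0.9934, "b2": -0.0651, "b3": -1.136}
  }
}
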