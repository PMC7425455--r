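{
  "id": "relative-risk-example-v1",
  "comment": "Editable example of per-factor relative-risk weights for the composite VRF score. Values follow commonly cited population relative risks for incident Alzheimer's disease; replace with the table appropriate to your study. Unit weights (all 1) reduce the composite to a simple factor count.",
  "diabetes": 1.46,
  "hypertension": 1.61,
  "smoking": 1.59,
  "depression": 1.65,
  "low_education": 1.59,
  "obesity": 1.60
}
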