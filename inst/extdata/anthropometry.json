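{
  "_provenance": "Segment masses as fractions of whole-body mass from standard anthropometric reference tables (Winter-type biomechanics tables); reference stature is the adult male average those tables assume.",
  "fractions": {
    "head_neck": 0.081,
    "arm": 0.05,
    "trunk": 0.497
  },
  "reference_stature_m": 1.74
}
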