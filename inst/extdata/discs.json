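{
  "_provenance": "Neutral-zone widths (deg) and post-neutral-zone rotational stiffnesses (N*m/deg) representative of in vitro lumbar functional-spine-unit bending tests; identical values applied at every lumbar level.",
  "default": {
    "neutral_zone_deg": { "frontal": 1.5, "axial": 1.0, "sagittal": 1.5 },
    "stiffness_nm_per_deg": { "frontal": 2.2, "axial": 3.0, "sagittal": 1.8 }
  }
}
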