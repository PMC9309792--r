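{
  "_provenance": "Breakpoint strains and forces are representative values in the range reported by cadaveric tensile tests of human spinal ligaments (toe-to-linear transition A, end of linear region B); pre-strains follow reported neutral-posture values, with the ligamentum flavum reduced to 5% to keep its forces physiological and the supraspinous ligament the only structure slack in neutral standing.",
  "systems": {
    "ALL": {
      "n": 1, "eps_pre": 0.05, "eps_A": 0.12, "eps_B": 0.30,
      "F_A": 120, "F_B": 330,
      "attach_sup": "body_ant_center", "attach_inf": "body_ant_center",
      "attach_inf_sacrum": "body_ant_center"
    },
    "PLL": {
      "n": 1, "eps_pre": 0.05, "eps_A": 0.11, "eps_B": 0.28,
      "F_A": 60, "F_B": 180,
      "attach_sup": "body_post_center", "attach_inf": "body_post_center",
      "attach_inf_sacrum": "body_post_center"
    },
    "LF": {
      "n": 2, "eps_pre": 0.05, "eps_A": 0.15, "eps_B": 0.35,
      "F_A": 80, "F_B": 240,
      "attach_sup": "arch_attach_center", "attach_inf": "arch_attach_center",
      "attach_inf_sacrum": "spinous_superior"
    },
    "ISL": {
      "n": 1, "eps_pre": 0.02, "eps_A": 0.14, "eps_B": 0.34,
      "F_A": 40, "F_B": 120,
      "attach_sup": "spinous_inferior", "attach_inf": "spinous_superior",
      "attach_inf_sacrum": "spinous_superior"
    },
    "SSL": {
      "n": 1, "eps_pre": -0.10, "eps_A": 0.20, "eps_B": 0.45,
      "F_A": 50, "F_B": 150,
      "attach_sup": "spinous_posterior", "attach_inf": "spinous_posterior",
      "attach_inf_sacrum": "spinous_posterior"
    }
  }
}
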