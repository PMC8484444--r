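{
  "species": "mexfly",
  "common_name": "Mexican fruit fly",
  "latin_name": "Anastrepha ludens",
  "stages": {
    "egg_larva":       {"delta": 258,  "theta_L": 10.3, "theta_U": 34, "b": 4, "a": 0.0018, "erlang_k": 25},
    "pupa":            {"delta": 264,  "theta_L": 10.3, "theta_U": 34, "b": 4, "a": 0.0018, "erlang_k": 40},
    "adult":           {"delta": 1000, "theta_L": 10.3, "theta_U": 34, "b": 4, "a": null,   "erlang_k": 68},
    "quiescent_adult": {"delta": 1000, "theta_L": 10.3, "theta_U": 34, "b": 4, "a": null,   "erlang_k": 68}
  },
  "rate_fits": [
    {"label": "E-P", "a": 0.0018, "stages": ["egg_larva", "pupa"], "audit": true}
  ],
  "reproduction": {
    "gamma": 2.355,
    "phi_base": 1.0475,
    "x0": 11,
    "x_ref": 11,
    "phiT":  {"form": "window", "lo": 12.78, "hi": 32.5},
    "phiRH": {"form": "scaled_medfly", "factor": 1.36},
    "sr": 0.5,
    "H": 500,
    "alpha_coeff": 0.005,
    "T_opt": 25
  },
  "mortality": {
    "groups": {
      "egg_larva": {"form": "piecewise_exp",
                    "T_break": 10.3,
                    "c1": 0.518,   "r1": -0.690312,
                    "c2": 0.00033, "r2": 0.1932889}
    },
    "stage_group": {
      "egg_larva": "egg_larva",
      "pupa": "egg_larva",
      "adult": "egg_larva",
      "quiescent_adult": "egg_larva"
    }
  }
}
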