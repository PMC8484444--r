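{
  "species": "oriental_fly",
  "common_name": "oriental fruit fly",
  "latin_name": "Bactrocera dorsalis",
  "stages": {
    "egg_larva":       {"delta": 136,  "theta_L": 8.87, "theta_U": 36.5, "b": 3.25, "a": 0.00305, "erlang_k": 25},
    "pupa":            {"delta": 177,  "theta_L": 8.87, "theta_U": 36.5, "b": 3.25, "a": 0.00305, "erlang_k": 25},
    "adult":           {"delta": 1050, "theta_L": 8.87, "theta_U": 36.5, "b": 3.25, "a": null,    "erlang_k": 71},
    "quiescent_adult": {"delta": 1532, "theta_L": 8.87, "theta_U": 36.5, "b": 3.25, "a": null,    "erlang_k": 71}
  },
  "rate_fits": [
    {"label": "E-P", "a": 0.00305, "stages": ["egg_larva", "pupa"], "audit": true}
  ],
  "reproduction": {
    "gamma": 2.3,
    "phi_base": 1.065,
    "x0": 16,
    "x_ref": 17.5,
    "phiT":  {"form": "poly", "coef": [-14.603, 1.6652, -0.0567, 0.0006]},
    "phiRH": {"form": "window", "lo": 40, "hi": 95},
    "sr": 0.5,
    "H": 500,
    "alpha_coeff": 0.005,
    "T_opt": 25
  },
  "mortality": {
    "groups": {
      "egg_larva": {"form": "poly",
                    "coef": [0.2486, -0.0308056, 0.0024931, -0.0001116, 0.0000018]}
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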