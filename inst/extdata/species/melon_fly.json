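{
  "species": "melon_fly",
  "common_name": "melon fly",
  "latin_name": "Bactrocera cucurbitae",
  "stages": {
    "egg_larva":       {"delta": 104,  "theta_L": 7.95, "theta_U": 33.5, "b": 4, "a": 0.00975, "erlang_k": 25},
    "pupa":            {"delta": 164,  "theta_L": 7.95, "theta_U": 33.5, "b": 4, "a": null,    "erlang_k": 40},
    "adult":           {"delta": 1197, "theta_L": 7.95, "theta_U": 33.5, "b": 4, "a": null,    "erlang_k": 70},
    "quiescent_adult": {"delta": 1197, "theta_L": 7.95, "theta_U": 33.5, "b": 4, "a": null,    "erlang_k": 70}
  },
  "rate_fits": [
    {"label": "E-L", "a": 0.00975, "stages": ["egg_larva"], "audit": true}
  ],
  "reproduction": {
    "gamma": 2.55,
    "phi_base": 1.065,
    "x0": 4,
    "x_ref": 4,
    "phiT":  {"form": "rational", "a": 0.0034, "theta_L": 13.3, "b": 1.85, "theta_U": 34.2},
    "phiRH": {"form": "window", "lo": 35, "hi": 100},
    "sr": 0.5,
    "H": 500,
    "alpha_coeff": 0.005,
    "T_opt": 25
  },
  "mortality": {
    "groups": {
      "egg_larva": {"form": "poly",
                    "coef": [0.0909, -0.02999476, 0.00349784, -0.00015536, 0.00000232]}
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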