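{
  "species": "medfly",
  "common_name": "Mediterranean fruit fly",
  "latin_name": "Ceratitis capitata",
  "stages": {
    "egg_larva":       {"delta": 129,  "theta_L": 10.345, "theta_U": 33.5, "b": 2.75, "a": 0.031,  "erlang_k": 25},
    "pupa":            {"delta": 165,  "theta_L": 9.5,    "theta_U": 33.7, "b": 4.8,  "a": 0.0059, "erlang_k": 40},
    "adult":           {"delta": 772,  "theta_L": 9.5,    "theta_U": 33.7, "b": 4.8,  "a": 0.0059, "erlang_k": 50},
    "quiescent_adult": {"delta": 1050, "theta_L": 9.5,    "theta_U": 33.7, "b": 4.8,  "a": null,   "erlang_k": 50}
  },
  "rate_fits": [
    {"label": "E-L", "a": 0.031,  "stages": ["egg_larva"], "audit": false},
    {"label": "P",   "a": 0.0059, "stages": ["pupa"],      "audit": true}
  ],
  "reproduction": {
    "gamma": 6.25,
    "phi_base": 1.088,
    "x0": 3,
    "x_ref": 3,
    "phiT":  {"form": "window", "lo": 15.0, "hi": 32.0},
    "phiRH": {"form": "poly",
              "coef": [0.15, 0.057917778, -0.001487393, 0.000016229, -0.000000063]},
    "sr": 0.5,
    "H": 500,
    "alpha_coeff": 0.005,
    "T_opt": 25
  },
  "mortality": {
    "groups": {
      "egg_larva":  {"form": "poly",
                     "coef": [1.16, -0.217793, 0.015014, -0.000444, 0.000005]},
      "pupa_adult": {"form": "poly",
                     "coef": [0.1846, -0.018705, 0.000487]}
    },
    "stage_group": {
      "egg_larva": "egg_larva",
      "pupa": "pupa_adult",
      "adult": "pupa_adult",
      "quiescent_adult": "pupa_adult"
    }
  }
}
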