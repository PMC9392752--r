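{
  "version": 1,
  "indices": ["cc", "pe", "npe", "fms"],
  "groups": [
    {"label": "control_children", "condition": "control", "age": "children",
     "n": 52, "n_alt": 42,
     "params": {"mu": 0.08, "phi": 0.37, "tau": 0.18, "lam": 0.17},
     "mean": {"cc": 5.06, "pe": 12.27, "npe": 14.13, "fms": 3.06},
     "sd": {"cc": 0.93, "pe": 3.26, "npe": 4.44, "fms": 1.75}},
    {"label": "control_teenagers", "condition": "control", "age": "teenagers",
     "n": 13, "n_alt": null,
     "params": {"mu": 0.17, "phi": 0.09, "tau": 0.12, "lam": 0.23},
     "mean": {"cc": 6.0, "pe": 10.08, "npe": 8.62, "fms": 0.38},
     "sd": {"cc": 0.0, "pe": 2.3, "npe": 3.36, "fms": 0.62}},
    {"label": "control_young_adults", "condition": "control", "age": "young_adults",
     "n": 10, "n_alt": null,
     "params": {"mu": 0.21, "phi": 0.73, "tau": 0.12, "lam": 0.33},
     "mean": {"cc": 5.9, "pe": 6.2, "npe": 8.5, "fms": 1.8},
     "sd": {"cc": 0.3, "pe": 1.89, "npe": 4.13, "fms": 1.72}},
    {"label": "control_middle_adults", "condition": "control", "age": "middle_adults",
     "n": 20, "n_alt": null,
     "params": {"mu": 0.05, "phi": 0.41, "tau": 0.18, "lam": 0.52},
     "mean": {"cc": 5.5, "pe": 7.9, "npe": 12.05, "fms": 2.7},
     "sd": {"cc": 0.81, "pe": 2.32, "npe": 3.53, "fms": 1.71}},
    {"label": "asc_children", "condition": "asc", "age": "children",
     "n": 26, "n_alt": null,
     "params": {"mu": 0.11, "phi": 0.93, "tau": 0.83, "lam": 0.01},
     "mean": {"cc": 0.12, "pe": 24.77, "npe": 38.04, "fms": 0.69},
     "sd": {"cc": 0.32, "pe": 4.48, "npe": 4.4, "fms": 1.1}},
    {"label": "asc_teenagers", "condition": "asc", "age": "teenagers",
     "n": 13, "n_alt": null,
     "params": {"mu": 0.20, "phi": 0.19, "tau": 0.14, "lam": 0.0},
     "mean": {"cc": 5.08, "pe": 12.77, "npe": 13.92, "fms": 2.85},
     "sd": {"cc": 1.21, "pe": 3.12, "npe": 3.12, "fms": 1.23}},
    {"label": "asc_young_adults", "condition": "asc", "age": "young_adults",
     "n": 9, "n_alt": null,
     "params": {"mu": 0.08, "phi": 0.11, "tau": 0.08, "lam": 0.02},
     "mean": {"cc": 5.44, "pe": 32.44, "npe": 14.33, "fms": 0.11},
     "sd": {"cc": 0.68, "pe": 10.23, "npe": 5.79, "fms": 0.31}},
    {"label": "asc_middle_adults", "condition": "asc", "age": "middle_adults",
     "n": 27, "n_alt": null,
     "params": {"mu": 0.20, "phi": 0.19, "tau": 0.14, "lam": 0.0},
     "mean": {"cc": 4.44, "pe": 12.93, "npe": 15.07, "fms": 3.11},
     "sd": {"cc": 1.03, "pe": 3.17, "npe": 4.29, "fms": 1.59}}
  ]
}
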