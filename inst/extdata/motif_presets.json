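{
  "fig4": {
    "motif": "m1",
    "integral_mode": "zero_order",
    "description": "m1 inflow/activation controller, set-point 3.0, step in k2, background k4",
    "pars": {"k1": 0.0, "k2": 1.0, "k3": 1.0, "k4": 0.0, "k5": 3.0, "k6": 1.0, "k7": 1e-6}
  },
  "fig6": {
    "motif": "m7",
    "integral_mode": "zero_order",
    "description": "m7 outflow/activation controller, set-point 3.0, step in k1, background k3",
    "pars": {"k1": 1.0, "k2": 0.0, "k3": 0.0, "k4": 0.03, "k5": 1.0, "k6": 31.0, "k7": 1e-6, "k8": 0.1}
  },
  "fig8": {
    "motif": "m2",
    "integral_mode": "zero_order",
    "description": "m2 inflow/derepression controller, set-point 3.0, step in k2, background k4",
    "pars": {"k1": 0.0, "k2": 1.0, "k3": 1e4, "k4": 0.0, "k5": 1.0, "k6": 3.0, "k7": 1e-6, "k8": 0.1}
  },
  "fig8_antithetic": {
    "motif": "m2",
    "integral_mode": "antithetic",
    "description": "m2 with antithetic (bimolecular) integral control, matched to the fig8 zero-order preset; k7 is the annihilation rate constant, chosen large so E1 removal operates in its zero-order regime",
    "pars": {"k1": 0.0, "k2": 1.0, "k3": 1e4, "k4": 0.0, "k5": 1.0, "k6": 3.0, "k7": 1e3, "k8": 0.1}
  },
  "fig11": {
    "motif": "m8",
    "integral_mode": "zero_order",
    "description": "m8 outflow/derepression controller, set-point 3.0, step in k1, background k3",
    "pars": {"k1": 1.0, "k2": 0.0, "k3": 0.0, "k4": 1e4, "k5": 620.0, "k6": 20.0, "k7": 1e-6, "k8": 0.1, "k9": 0.1}
  }
}
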