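{
  "condition": "atrophied",
  "version": "1",
  "specs": {
    "marrow": {
      "type": "cole_cole",
      "eps_inf": 12,
      "sigma_static": 0.0035,
      "delta_eps": 2000,
      "tau": 7.96e-06,
      "alpha": 0.1
    },
    "cortical_bone": {
      "type": "cole_cole",
      "eps_inf": 15,
      "sigma_static": 0.02,
      "delta_eps": 1000,
      "tau": 7.96e-06,
      "alpha": 0.2
    },
    "muscle": {
      "longitudinal": {
        "type": "cole_cole",
        "eps_inf": 108,
        "sigma_static": 0.45,
        "delta_eps": 45000,
        "tau": 1.59e-06,
        "alpha": 0.25
      },
      "transverse": {
        "type": "cole_cole",
        "eps_inf": 36,
        "sigma_static": 0.15,
        "delta_eps": 15000,
        "tau": 1.59e-06,
        "alpha": 0.25
      }
    },
    "skin_fat": {
      "type": "cole_cole",
      "eps_inf": 25,
      "sigma_static": 0.035,
      "delta_eps": 5000,
      "tau": 7.96e-06,
      "alpha": 0.2
    }
  }
}
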