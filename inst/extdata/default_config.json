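{
  "priors": {
    "a_max":    {"family": "truncated-normal", "mean": 1.0,   "sd": 0.5,   "lower": 0.01},
    "c0":       {"family": "truncated-normal", "mean": 0.0,   "sd": 0.5,   "lower": 0.0},
    "tau_r":    {"family": "truncated-normal", "mean": 0.004, "sd": 0.002, "lower": 2e-4},
    "tau_d":    {"family": "truncated-normal", "mean": 0.040, "sd": 0.020, "lower": 2e-3},
    "r0":       {"family": "gamma",            "shape": 1,    "rate": 1},
    "r1":       {"family": "gamma",            "shape": 2,    "rate": 0.1},
    "w01":      {"family": "gamma",            "shape": 1,    "rate": 1},
    "w10":      {"family": "gamma",            "shape": 2,    "rate": 1},
    "sigma2":   {"family": "inverse-gamma",    "shape": 2,    "rate": 0.1},
    "sigma2_b": {"family": "inverse-gamma",    "shape": 2,    "rate": 0.01}
  },
  "sampler": {
    "n_iterations": 1500,
    "burn_in": 300,
    "thinning": 1,
    "n_particles": 100,
    "s_max": 20,
    "seed": 1,
    "bursting": true,
    "update_sigma2_b": true,
    "exposure": "occupancy",
    "deterministic_start": false,
    "adapt": true,
    "mh_scale_frac": 0.1
  }
}
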