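{
  "trait": "demo_gaussian_trait",
  "family": "gaussian",
  "seed": 42,
  "out_dir": "urbanvar_demo_run",
  "simulate": {
    "n_individuals": [120, 320],
    "V_i": [1, 2],
    "V_r": [1, 1],
    "V_y": 0.1,
    "V_o": 0.1,
    "intercept": 10,
    "n_urban_locations": 8
  },
  "mcmc": { "n_iter": 1500, "burn_in": 500, "thin": 2 },
  "gradient": {
    "scales": [100, 250, 1000],
    "min_obs": 30,
    "responses": ["CV_P", "CV_I"],
    "n_iterations_used": 200,
    "draws_per_iteration": 20
  }
}
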