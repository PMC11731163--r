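{
  "task1": {"mean_A": 86, "mean_B": 94, "sd": 5},
  "task2": {"mean": 0, "sd_narrow": 3, "sd_broad": 12},
  "contrast_ladder": [0.004, 0.016, 0.033, 0.093, 0.18, 0.36, 0.72],
  "design_exp1": {"alpha_B": [0.75, 0.5, 0.25], "trials_per_block": 320, "n_sessions": 1},
  "design_exp2": {"alpha_B": [0.5, 0.5, 0.5], "trials_per_block": 320, "n_sessions": 2},
  "check_every": 80,
  "observer_defaults": {
    "noise_floor": 2, "noise_scale": 0.08, "noise_exponent": 0.9,
    "prior_weight": 1, "boundary_scale": 1, "noise_misestimate": 1,
    "lapse": 0.02, "gamble_weight": 1, "gamble_sd": 5
  },
  "analysis_defaults": {
    "correction": "loglinear", "accuracy_min": 0.6, "n_top_contrasts": 3,
    "c_error_max": 50, "k_error_max": 35, "k_max": 100, "sigma_max": 100,
    "bin_centers": [-14, -12, -10, -8, -6, -4, -2, 0, 2, 4, 6, 8, 10, 12, 14]
  }
}
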