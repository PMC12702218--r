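{
  "pipeline": {
    "fdr_alpha": 0.01,
    "ppm_tolerance": 10.0,
    "max_quant_ions": 5,
    "min_quant_ions": 3,
    "coelution_tolerance": 30,
    "cofragmentation_rule": "union",
    "correlation_aggregation": "min",
    "wide_scheme": {
      "start_mz": 400,
      "end_mz": 1000,
      "window_width": 16,
      "staggered": true
    }
  },
  "simulation": {
    "n_true_peptides": 200,
    "n_false_targets": 200,
    "n_decoys": 400,
    "matrices": ["urine", "plasma", "serum"],
    "detection_probability": { "urine": 0.9, "plasma": 0.75, "serum": 0.75 },
    "score_true": { "mean": 3.5, "sd": 1 },
    "score_null": { "mean": 0, "sd": 1 },
    "gradient_length": 5400,
    "rt_jitter_sd": 3,
    "peak_sigma": 6,
    "noise_sd": 0.1,
    "sample_step": 2,
    "n_interference_pairs": 15,
    "runs_per_matrix": 8,
    "fraction_spiked": 0.1,
    "fold_change": 2,
    "seed": 1
  }
}
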