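{
  "scenario": "null",
  "seed": 1,
  "n_positions": 200,
  "occurrence": 50,
  "min_len": 147,
  "max_len": 149,
  "period": 10.4,
  "baseline_regions": [[10, 29], [35, 74]],
  "dcc": {"max_dist": 100, "min_occurrence": 0},
  "classifier_threshold": 0.1,
  "alpha": 0.05
}
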