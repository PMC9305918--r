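[
  {"id": "population_ar_median", "metric": "t1", "value": 0.063, "cmp": "le_abs", "tol": 0.5},
  {"id": "population_din_median_mm", "metric": "t2", "value": 0.181, "cmp": "le_abs", "tol": 0.5},
  {"id": "noise_cnr266_ar_rel_pct", "metric": "t3", "value": 1.4, "cmp": "le_abs", "tol": 0.5},
  {"id": "noise_cnr266_din_rel_pct", "metric": "t4", "value": 3.3, "cmp": "le_abs", "tol": 0.5},
  {"id": "slice20_ar_rel_pct", "metric": "t5", "value": 1.5, "cmp": "le_abs", "tol": 0.5},
  {"id": "slice20_din_rel_pct", "metric": "t6", "value": 4.1, "cmp": "le_abs", "tol": 0.5},
  {"id": "bulk_rel_pct_bound", "metric": "t7", "value": 1.0, "cmp": "le", "tol": 0.5},
  {"id": "respiratory_ar_max_increase", "metric": "t8", "value": 0.031, "cmp": "le", "tol": 0.5},
  {"id": "respiratory_din_max_mm", "metric": "t9", "value": 0.6, "cmp": "le", "tol": 0.2},
  {"id": "respiratory_din_mean_mm", "metric": "t10", "value": 0.23, "cmp": "le_abs", "tol": 0.5}
]
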