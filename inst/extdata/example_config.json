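{
  "_comment": "Example run configuration. The consumption means/SDs below are ILLUSTRATIVE placeholders so the pipeline runs out of the box; they are NOT survey estimates. Replace them with values from a food-consumption database before drawing any conclusion.",
  "lod": 10,
  "loq": 30,
  "pool_categories": ["Biscuits", "Ground biscuits"],
  "age_groups": [
    {"label": "6 months", "body_weight": 8.0},
    {"label": "12 months", "body_weight": 9.4},
    {"label": "18 months", "body_weight": 10.9}
  ],
  "endpoints": [
    {"name": "neurotoxic", "bmdl10": 0.43, "concern_threshold": 125},
    {"name": "carcinogenic_harderian", "bmdl10": 0.17, "concern_threshold": 10000},
    {"name": "carcinogenic_mammary", "bmdl10": 0.31, "concern_threshold": 10000}
  ],
  "consumption": {
    "6 months":  {"mean_g_day": 15, "sd_g_day": 12},
    "12 months": {"mean_g_day": 22, "sd_g_day": 16},
    "18 months": {"mean_g_day": 28, "sd_g_day": 20}
  },
  "simulation": {
    "iterations": 10000,
    "bootstrap_replicates": 1000,
    "noise_sd": 4,
    "censoring_policy": "middle_bound",
    "master_seed": 20211201
  }
}
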