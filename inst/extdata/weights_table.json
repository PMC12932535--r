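{
  "comment": "Published evaluation index system: AHP dimension weights, within-dimension indicator weights and final (product) weights per age group. Final weights are the published rounded values; their grand totals are 1.001 (group4) and 1.000 (group5).",
  "dimension_weights": {
    "balance": 0.05,
    "spatial_orientation": 0.11,
    "rhythm": 0.17,
    "perceptual_judgment": 0.13,
    "body_coordination": 0.49,
    "limb_range": 0.05
  },
  "group4": {
    "x1":  {"indicator_weight": 0.273, "final_weight": 0.014},
    "x2":  {"indicator_weight": 0.253, "final_weight": 0.013},
    "x3":  {"indicator_weight": 0.224, "final_weight": 0.011},
    "x4":  {"indicator_weight": 0.250, "final_weight": 0.013},
    "x5":  {"indicator_weight": 0.317, "final_weight": 0.05},
    "x6":  {"indicator_weight": 0.213, "final_weight": 0.04},
    "x7":  {"indicator_weight": 0.166, "final_weight": 0.03},
    "x8":  {"indicator_weight": 0.304, "final_weight": 0.05},
    "x9":  {"indicator_weight": 0.332, "final_weight": 0.04},
    "x10": {"indicator_weight": 0.284, "final_weight": 0.03},
    "x11": {"indicator_weight": 0.255, "final_weight": 0.03},
    "x12": {"indicator_weight": 0.129, "final_weight": 0.01},
    "x13": {"indicator_weight": 0.277, "final_weight": 0.014},
    "x14": {"indicator_weight": 0.285, "final_weight": 0.014},
    "x15": {"indicator_weight": 0.230, "final_weight": 0.012},
    "x16": {"indicator_weight": 0.208, "final_weight": 0.010},
    "x17": {"indicator_weight": 0.358, "final_weight": 0.18},
    "x18": {"indicator_weight": 0.642, "final_weight": 0.31},
    "x19": {"indicator_weight": 0.614, "final_weight": 0.08},
    "x20": {"indicator_weight": 0.386, "final_weight": 0.05}
  },
  "group5": {
    "x1":  {"indicator_weight": 0.287, "final_weight": 0.014},
    "x2":  {"indicator_weight": 0.276, "final_weight": 0.014},
    "x3":  {"indicator_weight": 0.186, "final_weight": 0.009},
    "x4":  {"indicator_weight": 0.251, "final_weight": 0.013},
    "x5":  {"indicator_weight": 0.310, "final_weight": 0.053},
    "x6":  {"indicator_weight": 0.224, "final_weight": 0.038},
    "x7":  {"indicator_weight": 0.204, "final_weight": 0.035},
    "x8":  {"indicator_weight": 0.262, "final_weight": 0.045},
    "x9":  {"indicator_weight": 0.297, "final_weight": 0.03},
    "x10": {"indicator_weight": 0.278, "final_weight": 0.03},
    "x11": {"indicator_weight": 0.269, "final_weight": 0.03},
    "x12": {"indicator_weight": 0.156, "final_weight": 0.02},
    "x13": {"indicator_weight": 0.307, "final_weight": 0.015},
    "x14": {"indicator_weight": 0.306, "final_weight": 0.015},
    "x15": {"indicator_weight": 0.224, "final_weight": 0.011},
    "x16": {"indicator_weight": 0.163, "final_weight": 0.008},
    "x17": {"indicator_weight": 0.345, "final_weight": 0.17},
    "x18": {"indicator_weight": 0.655, "final_weight": 0.32},
    "x19": {"indicator_weight": 0.598, "final_weight": 0.08},
    "x20": {"indicator_weight": 0.402, "final_weight": 0.05}
  }
}
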