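{
  "comment": "Published sex differences (Cohen's d, female minus male, computed on unweighted level scores) per indicator and age group. Used as the synthetic generator's default planted effects (applied as latent mean shifts along the better direction). The 5-year table's row between x14 and x16 is mislabelled 'X20' in the source and is transcribed as x15.",
  "group4": {
    "x1": 0.05,  "x2": 0.14,  "x3": 0.43,  "x4": -0.13, "x5": 0.10,
    "x6": 0.20,  "x7": 0.03,  "x8": 0.16,  "x9": 0.03,  "x10": 0.13,
    "x11": 0.18, "x12": -0.28,"x13": 0.34, "x14": 0.21, "x15": 0.33,
    "x16": 0.23, "x17": 0.52, "x18": 0.25, "x19": -0.34,"x20": 0.11
  },
  "group5": {
    "x1": -0.13, "x2": -0.14, "x3": 0.22,  "x4": 0.13,  "x5": 0.11,
    "x6": 0.26,  "x7": 0.18,  "x8": 0.004, "x9": -0.15, "x10": -0.19,
    "x11": -0.06,"x12": -0.16,"x13": 0.67, "x14": 0.65, "x15": 0.19,
    "x16": 0.16, "x17": 0.04, "x18": 0.22, "x19": -0.23,"x20": -0.29
  }
}
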