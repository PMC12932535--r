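{
  "comment": "Published means/SDs of the coefficient-of-variation weighted indicators (body coordination and perceptual judgment), with the published CV values and within-dimension CV weights.",
  "group4": {
    "x17": {"mean": 11.726, "sd": 3.965,  "cv": 0.338, "cv_weight": 0.358},
    "x18": {"mean": 20.87,  "sd": 12.665, "cv": 0.607, "cv_weight": 0.642},
    "x19": {"mean": 35.400, "sd": 5.481,  "cv": 0.155, "cv_weight": 0.614},
    "x20": {"mean": 45.454, "sd": 4.423,  "cv": 0.097, "cv_weight": 0.386}
  },
  "group5": {
    "x17": {"mean": 8.840,  "sd": 2.366,  "cv": 0.268, "cv_weight": 0.345},
    "x18": {"mean": 28.56,  "sd": 14.499, "cv": 0.508, "cv_weight": 0.655},
    "x19": {"mean": 33.921, "sd": 6.308,  "cv": 0.186, "cv_weight": 0.598},
    "x20": {"mean": 37.592, "sd": 4.702,  "cv": 0.125, "cv_weight": 0.402}
  }
}
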