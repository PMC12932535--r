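{
  "comment": "Published five-level norm table, 5-year group (5.0-5.9 y). Same layout as the 4-year file. The printed fourth-band lower edges of x13/x14 ('-1.50') overlap the fifth band and are transcribed as the adjacent band edge 1.50 (dropped-sign misprint).",
  "age_group": "group5",
  "level_points": [20, 40, 60, 80, 100],
  "indicators": {
    "x1":  {"direction": "lower_is_better",  "floor": 10.32, "cuts": [8.48, 5.99, 4.36, 2.88],      "closures": ["ge","ge","ge","gt"], "weight": 0.014, "weighted_scores": [0.28, 0.56, 0.84, 1.12, 1.4]},
    "x2":  {"direction": "lower_is_better",  "floor": 11.70, "cuts": [8.52, 6.20, 5.10, 3.48],      "closures": ["ge","ge","ge","gt"], "weight": 0.014, "weighted_scores": [0.28, 0.56, 0.84, 1.12, 1.4]},
    "x3":  {"direction": "higher_is_better", "floor": 2.70,  "cuts": [4.65, 12.05, 22.97, 47.99],   "closures": ["ge","ge","ge","gt"], "weight": 0.009, "weighted_scores": [0.18, 0.36, 0.54, 0.72, 0.9]},
    "x4":  {"direction": "higher_is_better", "floor": 5.31,  "cuts": [7.30, 11.56, 20.60, 39.47],   "closures": ["ge","ge","ge","gt"], "weight": 0.013, "weighted_scores": [0.26, 0.52, 0.78, 1.04, 1.3]},
    "x5":  {"direction": "higher_is_better", "floor": 2.7,   "cuts": [3.0, 4.0, 4.7, 5],            "closures": ["ge","ge","ge","ge"], "weight": 0.053, "weighted_scores": [1.06, 2.12, 3.18, 4.24, 5.3]},
    "x6":  {"direction": "higher_is_better", "floor": 1,     "cuts": [2, 3, 4, 5],                  "closures": ["ge","ge","ge","ge"], "weight": 0.038, "weighted_scores": [0.76, 1.52, 2.28, 3.04, 3.8]},
    "x7":  {"direction": "higher_is_better", "floor": 1,     "cuts": [2, 3, 4, 5],                  "closures": ["ge","ge","ge","ge"], "weight": 0.035, "weighted_scores": [0.7, 1.4, 2.1, 2.8, 3.5]},
    "x8":  {"direction": "higher_is_better", "floor": 1,     "cuts": [2, 3, 4, 5],                  "closures": ["ge","ge","ge","ge"], "weight": 0.045, "weighted_scores": [0.9, 1.8, 2.7, 3.6, 4.5]},
    "x9":  {"direction": "lower_is_better",  "floor": 8.66,  "cuts": [7.91, 6.66, 6.00, 5.29],      "closures": ["ge","ge","ge","gt"], "weight": 0.03,  "weighted_scores": [0.6, 1.2, 1.8, 2.4, 3]},
    "x10": {"direction": "higher_is_better", "floor": 13,    "cuts": [18, 21, 24, 26],              "closures": ["ge","ge","ge","gt"], "weight": 0.03,  "weighted_scores": [0.6, 1.2, 1.8, 2.4, 3]},
    "x11": {"direction": "lower_is_better",  "floor": 21.17, "cuts": [18.32, 15.30, 13.10, 10.59],  "closures": ["ge","ge","ge","gt"], "weight": 0.03,  "weighted_scores": [0.6, 1.2, 1.8, 2.4, 3]},
    "x12": {"direction": "higher_is_better", "floor": 2,     "cuts": [4, 6, 8, 8],                  "closures": ["ge","ge","ge","gt"], "weight": 0.02,  "weighted_scores": [0.4, 0.8, 1.2, 1.6, 2]},
    "x13": {"direction": "higher_is_better", "floor": -9.5,  "cuts": [1.50, 3, 7.2, 14.1],          "closures": ["ge","ge","ge","gt"], "weight": 0.015, "weighted_scores": [0.3, 0.6, 0.9, 1.2, 1.5]},
    "x14": {"direction": "higher_is_better", "floor": -7.6,  "cuts": [1.50, 3, 7.3, 13.99],         "closures": ["ge","ge","ge","gt"], "weight": 0.015, "weighted_scores": [0.3, 0.6, 0.9, 1.2, 1.5]},
    "x15": {"direction": "lower_is_better",  "floor": 29,    "cuts": [23, 18, 13.8, 8.7],           "closures": ["ge","ge","ge","gt"], "weight": 0.011, "weighted_scores": [0.22, 0.44, 0.66, 0.88, 1.1]},
    "x16": {"direction": "lower_is_better",  "floor": 27,    "cuts": [22, 17, 13, 8.1],             "closures": ["ge","ge","ge","gt"], "weight": 0.008, "weighted_scores": [0.16, 0.32, 0.48, 0.64, 0.8]},
    "x17": {"direction": "lower_is_better",  "floor": 14.20, "cuts": [11.96, 9.47, 7.60, 6.04],     "closures": ["ge","ge","ge","gt"], "weight": 0.17,  "weighted_scores": [3.4, 6.8, 10.2, 13.6, 17]},
    "x18": {"direction": "higher_is_better", "floor": 4,     "cuts": [10, 21, 35, 47],              "closures": ["ge","ge","ge","gt"], "weight": 0.32,  "weighted_scores": [6.4, 12.8, 19.2, 25.6, 32]},
    "x19": {"direction": "lower_is_better",  "floor": 47.20, "cuts": [41.44, 35.95, 31.50, 26.51],  "closures": ["ge","ge","ge","gt"], "weight": 0.08,  "weighted_scores": [1.6, 3.2, 4.8, 6.4, 8]},
    "x20": {"direction": "lower_is_better",  "floor": 50,    "cuts": [44.25, 39, 35, 30.01],        "closures": ["ge","ge","ge","gt"], "weight": 0.05,  "weighted_scores": [1, 2, 3, 4, 5]}
  }
}
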