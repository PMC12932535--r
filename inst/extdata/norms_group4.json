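{
  "comment": "Published five-level norm table, 4-year group (4.0-4.9 y). 'floor' is the P3 no-score edge on the worse side; 'cuts' are the worse-side edges of levels 4,3,2,1 in raw units, ordered worst-to-best along the indicator's direction; closure 'ge' means a value exactly on the cut takes the better band, 'gt' that the better band is open at the cut (bands printed as strict '>'/'<'). weighted_scores are the published weighted level scores for points 20,40,60,80,100. x19/x20 store the centimeter bands; the auxiliary seconds figures printed alongside are not transcribed.",
  "age_group": "group4",
  "level_points": [20, 40, 60, 80, 100],
  "indicators": {
    "x1":  {"direction": "lower_is_better",  "floor": 11.24, "cuts": [8.66, 6.35, 4.41, 3.16],      "closures": ["ge","ge","ge","gt"], "weight": 0.014, "weighted_scores": [0.28, 0.56, 0.84, 1.12, 1.4]},
    "x2":  {"direction": "lower_is_better",  "floor": 12.50, "cuts": [8.97, 6.84, 5.35, 3.50],      "closures": ["ge","ge","ge","gt"], "weight": 0.013, "weighted_scores": [0.26, 0.52, 0.78, 1.04, 1.3]},
    "x3":  {"direction": "higher_is_better", "floor": 2.22,  "cuts": [3.76, 7.95, 13.49, 28.65],    "closures": ["ge","ge","ge","gt"], "weight": 0.011, "weighted_scores": [0.22, 0.44, 0.66, 0.88, 1.1]},
    "x4":  {"direction": "higher_is_better", "floor": 3.40,  "cuts": [6.84, 11.26, 19.50, 36.04],   "closures": ["ge","ge","ge","gt"], "weight": 0.013, "weighted_scores": [0.26, 0.52, 0.78, 1.04, 1.3]},
    "x5":  {"direction": "higher_is_better", "floor": 1.7,   "cuts": [2.7, 3.7, 4.3, 5],            "closures": ["ge","ge","ge","ge"], "weight": 0.05,  "weighted_scores": [1, 2, 3, 4, 5]},
    "x6":  {"direction": "higher_is_better", "floor": 1,     "cuts": [2, 3, 4, 5],                  "closures": ["ge","ge","ge","ge"], "weight": 0.04,  "weighted_scores": [0.8, 1.6, 2.4, 3.2, 4]},
    "x7":  {"direction": "higher_is_better", "floor": 1,     "cuts": [2, 3, 4, 5],                  "closures": ["ge","ge","ge","ge"], "weight": 0.03,  "weighted_scores": [0.6, 1.2, 1.8, 2.4, 3]},
    "x8":  {"direction": "higher_is_better", "floor": 1,     "cuts": [2, 3, 4, 5],                  "closures": ["ge","ge","ge","ge"], "weight": 0.05,  "weighted_scores": [1, 2, 3, 4, 5]},
    "x9":  {"direction": "lower_is_better",  "floor": 9.81,  "cuts": [8.71, 7.17, 6.34, 5.59],      "closures": ["ge","ge","ge","gt"], "weight": 0.04,  "weighted_scores": [0.8, 1.6, 2.4, 3.2, 4]},
    "x10": {"direction": "higher_is_better", "floor": 11,    "cuts": [14, 19, 22, 24],              "closures": ["ge","ge","ge","gt"], "weight": 0.03,  "weighted_scores": [0.6, 1.2, 1.8, 2.4, 3]},
    "x11": {"direction": "lower_is_better",  "floor": 24.29, "cuts": [22.42, 18.50, 15.85, 13.28],  "closures": ["ge","ge","ge","gt"], "weight": 0.03,  "weighted_scores": [0.6, 1.2, 1.8, 2.4, 3]},
    "x12": {"direction": "higher_is_better", "floor": 1,     "cuts": [3, 5, 7, 7],                  "closures": ["ge","ge","ge","gt"], "weight": 0.01,  "weighted_scores": [0.2, 0.4, 0.6, 0.8, 1]},
    "x13": {"direction": "higher_is_better", "floor": -2.79, "cuts": [1.45, 4, 8, 11.99],           "closures": ["ge","ge","ge","gt"], "weight": 0.014, "weighted_scores": [0.28, 0.56, 0.84, 1.12, 1.4]},
    "x14": {"direction": "higher_is_better", "floor": -2.30, "cuts": [1.40, 4, 8, 12.99],           "closures": ["ge","ge","ge","gt"], "weight": 0.014, "weighted_scores": [0.28, 0.56, 0.84, 1.12, 1.4]},
    "x15": {"direction": "lower_is_better",  "floor": 27,    "cuts": [25, 20, 16, 11.1],            "closures": ["ge","ge","ge","gt"], "weight": 0.012, "weighted_scores": [0.24, 0.48, 0.72, 0.96, 1.2]},
    "x16": {"direction": "lower_is_better",  "floor": 26.8,  "cuts": [24, 19, 15, 10.1],            "closures": ["ge","ge","ge","gt"], "weight": 0.010, "weighted_scores": [0.2, 0.4, 0.6, 0.8, 1]},
    "x17": {"direction": "lower_is_better",  "floor": 21.84, "cuts": [17.47, 12.61, 9.80, 7.48],    "closures": ["ge","ge","ge","gt"], "weight": 0.18,  "weighted_scores": [3.6, 7.2, 10.8, 14.4, 18]},
    "x18": {"direction": "higher_is_better", "floor": 2,     "cuts": [5, 14, 26, 38],               "closures": ["ge","ge","ge","gt"], "weight": 0.31,  "weighted_scores": [6.2, 12.4, 18.6, 24.8, 31]},
    "x19": {"direction": "lower_is_better",  "floor": 49.37, "cuts": [44.19, 37, 33.30, 29.13],     "closures": ["ge","ge","ge","gt"], "weight": 0.08,  "weighted_scores": [1.6, 3.2, 4.8, 6.4, 8]},
    "x20": {"direction": "lower_is_better",  "floor": 54,    "cuts": [50, 47.60, 42.53, 39.21],     "closures": ["ge","ge","ge","gt"], "weight": 0.05,  "weighted_scores": [1, 2, 3, 4, 5]}
  }
}
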