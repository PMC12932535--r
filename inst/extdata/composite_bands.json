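{
  "comment": "Published comprehensive (composite) classification tables. Each entry gives the three cut points [Excellent, Good, Qualified] at the P90/P65/P15 percentiles of the modeling sample; a score at or above a cut takes the better band; below the last cut is Unqualified. Theoretical shares are 10/25/50/15 percent. Cut points for the weighted dimension subtotals are kept for reference; several printed dimension cells are garbled in the source table and transcribed as printed.",
  "theoretical_percent": [10, 25, 50, 15],
  "percentile_anchors": [90, 65, 15],
  "group4": {
    "n_modeling": 426,
    "composite": [76.05, 67.01, 51.40],
    "dimensions": {
      "balance":             [4.07, 3.33, 2.30],
      "rhythm":              [16, 14, 6.40],
      "spatial_orientation": [8.80, 7.20, 5.00],
      "limb_range":          [4.20, 3.52, 2.08],
      "body_coordination":   [39.98, 33, 19.65],
      "perceptual_judgment": [11.40, 9.80, 6.20]
    }
  },
  "group5": {
    "n_modeling": 416,
    "composite": [75.56, 67.95, 50],
    "dimensions": {
      "balance":             [3.81, 3.21, 2.20],
      "rhythm":              [16.05, 14.58, 8.70],
      "spatial_orientation": [8.20, 7.11, 4.80],
      "limb_range":          [4.08, 3.31, 2.10],
      "body_coordination":   [42.1, 32.8, 19.5],
      "perceptual_judgment": [10.5, 8.5, 4.0]
    }
  }
}
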