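{
  "comment": "Published principal-component weighting worked example for the balance dimension. The eigenvalue/variance table is transcribed verbatim even though it is internally inconsistent in the source (roots sum to 4.2; the third root does not match its variance share); it is a fixture input, not a regenerable quantity. The 5-year balance composite coefficients and weights are included for cross-checks.",
  "group4": {
    "kmo": 0.721,
    "eigenvalues": [1.887, 1.231, 0.897, 0.185],
    "variance_pct": [47.185, 35.778, 12.414, 4.623],
    "cumulative_pct": [47.185, 82.963, 95.377, 100.000],
    "loadings": {
      "x1": [0.936, -0.028],
      "x2": [0.932, -0.094],
      "x3": [-0.080, 0.880],
      "x4": [0.370, 0.497]
    },
    "coefficients": {
      "x1": [0.681, -0.025],
      "x2": [0.678, -0.084],
      "x3": [-0.058, 0.793],
      "x4": [0.269, 0.447]
    },
    "composite_coefficients": {"x1": 0.377, "x2": 0.349, "x3": 0.309, "x4": 0.346},
    "weights": {"x1": 0.273, "x2": 0.253, "x3": 0.224, "x4": 0.250}
  },
  "group5": {
    "composite_coefficients": {"x1": 0.419, "x2": 0.403, "x3": 0.271, "x4": 0.368},
    "weights": {"x1": 0.287, "x2": 0.276, "x3": 0.186, "x4": 0.251}
  }
}
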