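{
  "comment": "Indicator catalogue for the coordination-ability instrument. Dimension membership and weights follow the published index system; directions follow the monotone ordering of the published norm bands. Names marked provisional are inferred from the battery description; ids are authoritative.",
  "dimensions": ["balance", "rhythm", "spatial_orientation", "limb_range", "body_coordination", "perceptual_judgment"],
  "indicators": [
    {"id": "x1",  "name": "Tiptoe straight-line walk",                  "provisional": false, "dimension": "balance",             "unit": "seconds",    "direction": "lower_is_better"},
    {"id": "x2",  "name": "Heel walk",                                  "provisional": false, "dimension": "balance",             "unit": "seconds",    "direction": "lower_is_better"},
    {"id": "x3",  "name": "Single-leg stance",                          "provisional": false, "dimension": "balance",             "unit": "seconds",    "direction": "higher_is_better"},
    {"id": "x4",  "name": "Eyes-closed marching in place",              "provisional": false, "dimension": "balance",             "unit": "seconds",    "direction": "higher_is_better"},
    {"id": "x5",  "name": "Rhythm perception rating",                   "provisional": true,  "dimension": "rhythm",              "unit": "rating_1_5", "direction": "higher_is_better"},
    {"id": "x6",  "name": "Rhythmic sequence reproduction",             "provisional": false, "dimension": "rhythm",              "unit": "rating_1_5", "direction": "higher_is_better"},
    {"id": "x7",  "name": "Rhythm item rating (untitled)",              "provisional": true,  "dimension": "rhythm",              "unit": "rating_1_5", "direction": "higher_is_better"},
    {"id": "x8",  "name": "Rhythm item rating (untitled)",              "provisional": true,  "dimension": "rhythm",              "unit": "rating_1_5", "direction": "higher_is_better"},
    {"id": "x9",  "name": "Curve walking",                              "provisional": true,  "dimension": "spatial_orientation", "unit": "seconds",    "direction": "lower_is_better"},
    {"id": "x10", "name": "Repeated side sliding steps",                "provisional": true,  "dimension": "spatial_orientation", "unit": "count",      "direction": "higher_is_better"},
    {"id": "x11", "name": "Turning and changing direction in place",    "provisional": true,  "dimension": "spatial_orientation", "unit": "seconds",    "direction": "lower_is_better"},
    {"id": "x12", "name": "Directional kicking",                        "provisional": false, "dimension": "spatial_orientation", "unit": "count",      "direction": "higher_is_better"},
    {"id": "x13", "name": "Single-leg seated forward bend (left)",      "provisional": false, "dimension": "limb_range",          "unit": "centimeters","direction": "higher_is_better"},
    {"id": "x14", "name": "Single-leg seated forward bend (right)",     "provisional": false, "dimension": "limb_range",          "unit": "centimeters","direction": "higher_is_better"},
    {"id": "x15", "name": "Shoulder flexibility (left arm)",            "provisional": true,  "dimension": "limb_range",          "unit": "centimeters","direction": "lower_is_better"},
    {"id": "x16", "name": "Shoulder flexibility (right arm)",           "provisional": true,  "dimension": "limb_range",          "unit": "centimeters","direction": "lower_is_better"},
    {"id": "x17", "name": "Jump square",                                "provisional": false, "dimension": "body_coordination",   "unit": "seconds",    "direction": "lower_is_better"},
    {"id": "x18", "name": "Fist-kick alternation count",                "provisional": true,  "dimension": "body_coordination",   "unit": "count",      "direction": "higher_is_better"},
    {"id": "x19", "name": "Hand reaction (ruler drop)",                 "provisional": false, "dimension": "perceptual_judgment", "unit": "centimeters","direction": "lower_is_better"},
    {"id": "x20", "name": "Foot reaction (ruler drop)",                 "provisional": false, "dimension": "perceptual_judgment", "unit": "centimeters","direction": "lower_is_better"}
  ]
}
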