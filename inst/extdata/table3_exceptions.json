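{
  "comment": "Cells of the published RISC II score table whose printed score point or odds ratio is inconsistent with the printed coefficient (score != round(coefficient, 1) or OR != round(exp(coefficient), 2)). Printed values are kept verbatim in the bundled model; see published_model_exceptions().",
  "exceptions": [
    {"variable": "second_worst_injury", "label": "0-2",    "field": "score", "printed": 0.2,  "implied": 0.3},
    {"variable": "age",                 "label": "80-84",  "field": "score", "printed": -2.4, "implied": -2.2},
    {"variable": "age",                 "label": "80-84",  "field": "or",    "printed": 0.09, "implied": 0.11},
    {"variable": "pupil_reactivity",    "label": "brisk",  "field": "score", "printed": 0.2,  "implied": 0.3},
    {"variable": "pupil_size",          "label": "normal", "field": "or",    "printed": 1.2,  "implied": 1.19},
    {"variable": "haemoglobin",         "label": "<7.0",   "field": "score", "printed": -0.5, "implied": -0.6}
  ]
}
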