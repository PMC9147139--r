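{
  "comment": "Admissible ranges of continuous variables checked before score calculation. Bounds are inclusive. The HF-duration upper bound is dynamic: the patient's own age in years times 12 months.",
  "static": [
    {"variable": "age",         "lower": 18,     "upper": 110,    "unit": "years"},
    {"variable": "bmi",         "lower": 14,     "upper": 60,     "unit": "kg/m2"},
    {"variable": "systolic_bp", "lower": 70,     "upper": 250,    "unit": "mm Hg"},
    {"variable": "lvef",        "lower": 4,      "upper": 85,     "unit": "%"},
    {"variable": "creatinine",  "lower": 26.526, "upper": 1326.3, "unit": "umol/L"},
    {"variable": "sodium",      "lower": 120,    "upper": 150,    "unit": "mmol/L"},
    {"variable": "hemoglobin",  "lower": 5,      "upper": 20,     "unit": "g/dL"},
    {"variable": "egfr",        "lower": 5,      "upper": 120,    "unit": "mL/min/1.73"}
  ],
  "hf_duration": {"lower": 0, "upper_per_age_year": 12, "unit": "months"}
}
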