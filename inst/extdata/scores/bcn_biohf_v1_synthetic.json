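{
  "score_id": "bcn_biohf_v1_synthetic",
  "method": "cox_lp",
  "description": "SYNTHETIC STAND-IN for the Barcelona Bio-HF v1 calculator (the biomarker-free Cox model). The variable set, the Cox linear-predictor mechanics, the baseline survivals per horizon and the reference-value imputation policy mirror the published calculator's structure, but the numeric coefficients are NOT the published ones: the original model coefficients are not reproduced here and the values below are directionally-plausible placeholders for engine validation only. Do not use for clinical prediction.",
  "horizons": [1, 2, 3],
  "completeness": "allow_imputation",
  "variables": [
    {"name": "age",                  "kind": "continuous", "clip_lower": 20,  "clip_upper": 90},
    {"name": "lvef",                 "kind": "continuous", "clip_lower": 10,  "clip_upper": 70},
    {"name": "sodium",               "kind": "continuous", "clip_lower": 125, "clip_upper": 145},
    {"name": "hemoglobin",           "kind": "continuous", "clip_lower": 8,   "clip_upper": 17},
    {"name": "egfr",                 "kind": "continuous", "clip_lower": 10,  "clip_upper": 90},
    {"name": "furosemide_equiv_dose","kind": "continuous", "clip_lower": 0,   "clip_upper": 500},
    {"name": "sex",                  "kind": "categorical"},
    {"name": "nyha",                 "kind": "categorical"},
    {"name": "beta_blocker",         "kind": "boolean"},
    {"name": "acei_arb",             "kind": "boolean"},
    {"name": "statin",               "kind": "boolean"}
  ],
  "terms": [
    {"variable": "age",        "type": "linear", "coef": 0.04},
    {"variable": "lvef",       "type": "linear", "coef": -0.02},
    {"variable": "sodium",     "type": "linear", "coef": -0.04},
    {"variable": "hemoglobin", "type": "linear", "coef": -0.12},
    {"variable": "egfr",       "type": "linear", "coef": -0.012},
    {"variable": "sex",  "type": "categorical", "map": {"female": -0.35, "male": 0}},
    {"variable": "nyha", "type": "categorical", "map": {"1": 0, "2": 0.3, "3": 0.7, "4": 1.0}},
    {"variable": "beta_blocker", "type": "boolean", "true": -0.4,  "false": 0},
    {"variable": "acei_arb",     "type": "boolean", "true": -0.3,  "false": 0},
    {"variable": "statin",       "type": "boolean", "true": -0.25, "false": 0},
    {"variable": "furosemide_equiv_dose", "type": "bands",
     "bands": [
       {"min": null, "max": 0.0001, "coef": 0},
       {"min": 0.0001, "max": 40.0001, "coef": 0.25},
       {"min": 40.0001, "max": null, "coef": 0.6}
     ]}
  ],
  "center": -6.26,
  "baseline_survival": {"1": 0.93, "2": 0.87, "3": 0.81},
  "imputation": {
    "lvef": 35,
    "sodium": 139,
    "hemoglobin": 13,
    "egfr": 60,
    "nyha": 2
  }
}
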