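{
  "score_id": "maggic",
  "method": "points_table",
  "description": "Additive integer points score for all-cause mortality in chronic heart failure (13 clinical variables; age and systolic blood pressure points are stratified by ejection-fraction band). Requires complete data; no imputation. Points tables and the integer-score to probability lookup transcribed from the published score.",
  "horizons": [1, 3],
  "completeness": "require_complete",
  "clamp_points": true,
  "variables": [
    {"name": "lvef",              "kind": "continuous", "clip_lower": 1,  "clip_upper": 95},
    {"name": "age",               "kind": "continuous", "clip_lower": 18, "clip_upper": 110},
    {"name": "systolic_bp",       "kind": "continuous", "clip_lower": 50, "clip_upper": 250},
    {"name": "bmi",               "kind": "continuous", "clip_lower": 10, "clip_upper": 50},
    {"name": "creatinine",        "kind": "continuous", "clip_lower": 20, "clip_upper": 1400},
    {"name": "nyha",              "kind": "categorical"},
    {"name": "sex",               "kind": "categorical"},
    {"name": "current_smoker",    "kind": "boolean"},
    {"name": "diabetes",          "kind": "boolean"},
    {"name": "copd",              "kind": "boolean"},
    {"name": "hf_duration_ge_18", "kind": "boolean"},
    {"name": "beta_blocker",      "kind": "boolean"},
    {"name": "acei_arb",          "kind": "boolean"}
  ],
  "points": [
    {
      "variable": "lvef", "type": "bands",
      "bands": [
        {"min": null, "max": 20, "points": 7},
        {"min": 20, "max": 25, "points": 6},
        {"min": 25, "max": 30, "points": 5},
        {"min": 30, "max": 35, "points": 3},
        {"min": 35, "max": 40, "points": 2},
        {"min": 40, "max": null, "points": 0}
      ]
    },
    {
      "variable": "age", "type": "stratified_bands", "stratifier": "lvef",
      "strata": [
        {
          "min": null, "max": 30,
          "bands": [
            {"min": null, "max": 55, "points": 0},
            {"min": 55, "max": 60, "points": 1},
            {"min": 60, "max": 65, "points": 2},
            {"min": 65, "max": 70, "points": 4},
            {"min": 70, "max": 75, "points": 6},
            {"min": 75, "max": 80, "points": 8},
            {"min": 80, "max": null, "points": 10}
          ]
        },
        {
          "min": 30, "max": 40,
          "bands": [
            {"min": null, "max": 55, "points": 0},
            {"min": 55, "max": 60, "points": 2},
            {"min": 60, "max": 65, "points": 4},
            {"min": 65, "max": 70, "points": 6},
            {"min": 70, "max": 75, "points": 8},
            {"min": 75, "max": 80, "points": 10},
            {"min": 80, "max": null, "points": 13}
          ]
        },
        {
          "min": 40, "max": null,
          "bands": [
            {"min": null, "max": 55, "points": 0},
            {"min": 55, "max": 60, "points": 3},
            {"min": 60, "max": 65, "points": 5},
            {"min": 65, "max": 70, "points": 7},
            {"min": 70, "max": 75, "points": 9},
            {"min": 75, "max": 80, "points": 12},
            {"min": 80, "max": null, "points": 15}
          ]
        }
      ]
    },
    {
      "variable": "systolic_bp", "type": "stratified_bands", "stratifier": "lvef",
      "strata": [
        {
          "min": null, "max": 30,
          "bands": [
            {"min": null, "max": 110, "points": 5},
            {"min": 110, "max": 120, "points": 4},
            {"min": 120, "max": 130, "points": 3},
            {"min": 130, "max": 140, "points": 2},
            {"min": 140, "max": 150, "points": 1},
            {"min": 150, "max": null, "points": 0}
          ]
        },
        {
          "min": 30, "max": 40,
          "bands": [
            {"min": null, "max": 110, "points": 3},
            {"min": 110, "max": 120, "points": 2},
            {"min": 120, "max": 130, "points": 1},
            {"min": 130, "max": 140, "points": 1},
            {"min": 140, "max": 150, "points": 0},
            {"min": 150, "max": null, "points": 0}
          ]
        },
        {
          "min": 40, "max": null,
          "bands": [
            {"min": null, "max": 110, "points": 2},
            {"min": 110, "max": 120, "points": 1},
            {"min": 120, "max": 130, "points": 1},
            {"min": 130, "max": 140, "points": 0},
            {"min": 140, "max": 150, "points": 0},
            {"min": 150, "max": null, "points": 0}
          ]
        }
      ]
    },
    {
      "variable": "bmi", "type": "bands",
      "bands": [
        {"min": null, "max": 15, "points": 6},
        {"min": 15, "max": 20, "points": 5},
        {"min": 20, "max": 25, "points": 3},
        {"min": 25, "max": 30, "points": 2},
        {"min": 30, "max": null, "points": 0}
      ]
    },
    {
      "variable": "creatinine", "type": "bands",
      "bands": [
        {"min": null, "max": 90, "points": 0},
        {"min": 90, "max": 110, "points": 1},
        {"min": 110, "max": 130, "points": 2},
        {"min": 130, "max": 150, "points": 3},
        {"min": 150, "max": 170, "points": 4},
        {"min": 170, "max": 210, "points": 5},
        {"min": 210, "max": 250, "points": 6},
        {"min": 250, "max": null, "points": 8}
      ]
    },
    {"variable": "nyha", "type": "categorical",
     "map": {"1": 0, "2": 2, "3": 6, "4": 8}},
    {"variable": "sex", "type": "categorical",
     "map": {"female": 0, "male": 1}},
    {"variable": "current_smoker", "type": "boolean", "true": 1, "false": 0},
    {"variable": "diabetes", "type": "boolean", "true": 3, "false": 0},
    {"variable": "copd", "type": "boolean", "true": 2, "false": 0},
    {"variable": "hf_duration_ge_18", "type": "boolean", "true": 2, "false": 0},
    {"variable": "beta_blocker", "type": "boolean", "true": 0, "false": 3},
    {"variable": "acei_arb", "type": "boolean", "true": 0, "false": 1}
  ],
  "risk_lookup": {
    "points": [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17,
               18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29, 30, 31, 32, 33,
               34, 35, 36, 37, 38, 39, 40, 41, 42, 43, 44, 45, 46, 47, 48, 49, 50],
    "risk": {
      "1": [0.015, 0.016, 0.018, 0.020, 0.022, 0.024, 0.027, 0.029, 0.032,
            0.036, 0.039, 0.043, 0.048, 0.052, 0.058, 0.063, 0.070, 0.077,
            0.084, 0.093, 0.102, 0.111, 0.122, 0.134, 0.147, 0.160, 0.175,
            0.191, 0.209, 0.227, 0.247, 0.269, 0.292, 0.316, 0.342, 0.369,
            0.398, 0.427, 0.458, 0.490, 0.523, 0.556, 0.590, 0.625, 0.658,
            0.692, 0.725, 0.756, 0.787, 0.815, 0.842],
      "3": [0.039, 0.043, 0.048, 0.052, 0.058, 0.063, 0.070, 0.077, 0.084,
            0.093, 0.102, 0.111, 0.122, 0.134, 0.147, 0.160, 0.175, 0.191,
            0.209, 0.227, 0.247, 0.269, 0.292, 0.316, 0.342, 0.369, 0.398,
            0.427, 0.458, 0.490, 0.523, 0.556, 0.590, 0.625, 0.658, 0.692,
            0.725, 0.756, 0.787, 0.815, 0.842, 0.866, 0.889, 0.908, 0.926,
            0.941, 0.953, 0.964, 0.973, 0.980, 0.985]
    }
  }
}
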