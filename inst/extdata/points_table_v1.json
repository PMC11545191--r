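{
  "version": 1,
  "description": "Sex-specific risk-factor point bands for the heart-age calculator, plus atherogenic-index category thresholds. Printed bands are normalized to half-open real intervals [lower, upper) so every positive measurement falls in exactly one band. 'breaks' are the interior band edges; 'points' has length(breaks)+1, ordered from the band below the first break upward.",
  "male": {
    "total_chol": { "breaks": [130, 146, 161, 176, 191, 200, 240], "points": [-5, -4, -3, -2, -1, 0, 1, 2] },
    "hdl":        { "breaks": [35, 40, 46, 51, 56, 61, 66],        "points": [2, 1, 0, -1, -2, -3, -4, -5] },
    "glucose":    { "breaks": [70, 81, 91, 100, 110, 126],         "points": [-5, -3, -2, 0, 2, 3, 5], "treated_points": 5 },
    "smoker":     { "yes": 5, "no": 0 },
    "bmi":        { "breaks": [20, 22.6, 25, 30, 35],              "points": [-2, -1, 0, 1, 2, 3] },
    "bp":         { "sbp_breaks": [120, 140, 160], "dbp_breaks": [80, 90, 100], "points": [-3, 0, 2, 3], "treated_points": 3 }
  },
  "female": {
    "total_chol": { "breaks": [130, 146, 161, 176, 191, 200, 240], "points": [-5, -4, -3, -2, -1, 0, 1, 2] },
    "hdl":        { "breaks": [40, 50, 56, 61, 66, 71, 76],        "points": [2, 1, 0, -1, -2, -3, -4, -5] },
    "glucose":    { "breaks": [70, 81, 91, 100, 110, 126],         "points": [-5, -3, -2, 0, 2, 3, 5], "treated_points": 5 },
    "smoker":     { "yes": 5, "no": 0 },
    "bmi":        { "breaks": [20, 22.6, 25, 30, 35],              "points": [-2, -1, 0, 1, 2, 3] },
    "bp":         { "sbp_breaks": [120, 140, 160], "dbp_breaks": [80, 90, 100], "points": [-3, 0, 2, 3], "treated_points": 3 }
  },
  "clamp": { "lower": -20, "upper": 19 },
  "high_ally_cutoff": 17,
  "atherogenic": {
    "tc_hdl": {
      "male":   { "low_below": 5.0, "high_above": 9.0 },
      "female": { "low_below": 4.5, "high_above": 7.0 }
    },
    "ldl_hdl": { "high_at": 3.0 },
    "tg_hdl":  { "high_at": 3.0 }
  }
}
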