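{
  "marker": "PlGF",
  "note": "Placental growth factor distribution parameters: regressed affected median MoM by completed week (evaluated at week + 3 days), probability-plot SDs of log10 MoM, MoM truncation limits, gestational-age median trends and covariate adjustment divisors.",
  "first_trimester": {
    "affected_median_mom": {"11": 0.85, "12": 0.72, "13": 0.61},
    "affected_median_ci": {
      "11": [0.76, 0.95],
      "12": [0.68, 0.76],
      "13": [0.55, 0.67]
    },
    "sd_log10": {"affected": 0.1705, "unaffected": 0.1556},
    "truncation_mom": [0.4, 2.5],
    "affected_weekly_ratio": 0.85,
    "unaffected_weekly_growth": 0.31
  },
  "second_trimester": {
    "affected_median_mom": {"14": 0.69, "15": 0.77, "16": 0.85},
    "affected_median_ci": {
      "14": [0.54, 0.89],
      "15": [0.65, 0.91],
      "16": [0.75, 0.97]
    },
    "sd_log10": {"affected": 0.2243, "unaffected": 0.1786},
    "truncation_mom": [0.4, 2.5],
    "affected_weekly_ratio": 1.11,
    "unaffected_weekly_growth": 0.19
  },
  "covariates": {
    "first_trimester": {
      "smoking_divisor": 1.32,
      "ethnicity_divisors": {"afro_caribbean": 1.18},
      "weight_per5kg": -0.013
    },
    "second_trimester": {
      "smoking_divisor": 1.36,
      "ethnicity_divisors": {"afro_caribbean": 1.30},
      "weight_per5kg": -0.031
    }
  }
}
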