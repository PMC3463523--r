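{
  "note": "SYNTHETIC parameter set for the standard Down syndrome screening markers (NT, PAPP-A, free beta-hCG, AFP, uE3, inhibin-A) and their correlations with PlGF. These are representative values assembled from the published screening literature (single-marker detection rates, truncated-scale SDs and standard correlation tables), NOT a transcription of any single study's appendix; absolute performance figures computed from them are indicative only. Means are log10 of the affected median MoM (unaffected means are 0); SDs are log10 MoM; truncation limits are on the MoM scale.",
  "week_second_default": 15,
  "markers": {
    "NT": {
      "trimester": "first",
      "affected_median_mom": {"11": 1.88, "12": 1.74, "13": 1.62},
      "sd_log10": {"affected": 0.22, "unaffected": 0.10},
      "truncation_mom": [0.5, 3.0]
    },
    "PAPP_A": {
      "trimester": "first",
      "affected_median_mom": {"11": 0.41, "12": 0.47, "13": 0.54},
      "sd_log10": {"affected": 0.31, "unaffected": 0.25},
      "truncation_mom": [0.2, 5.0]
    },
    "free_bhCG_1": {
      "trimester": "first",
      "affected_median_mom": {"11": 1.79, "12": 1.98, "13": 2.09},
      "sd_log10": {"affected": 0.28, "unaffected": 0.27},
      "truncation_mom": [0.2, 5.0]
    },
    "AFP": {
      "trimester": "second",
      "affected_median_mom": {"all": 0.715},
      "sd_log10": {"affected": 0.19, "unaffected": 0.146},
      "truncation_mom": [0.25, 2.5]
    },
    "uE3": {
      "trimester": "second",
      "affected_median_mom": {"all": 0.69},
      "sd_log10": {"affected": 0.13, "unaffected": 0.12},
      "truncation_mom": [0.3, 2.0]
    },
    "free_bhCG_2": {
      "trimester": "second",
      "affected_median_mom": {"all": 2.06},
      "sd_log10": {"affected": 0.26, "unaffected": 0.25},
      "truncation_mom": [0.2, 5.0]
    },
    "inhibin_A": {
      "trimester": "second",
      "affected_median_mom": {"all": 1.90},
      "sd_log10": {"affected": 0.22, "unaffected": 0.18},
      "truncation_mom": [0.3, 5.0]
    }
  },
  "correlation_order": ["NT", "PAPP_A", "free_bhCG_1", "PlGF_1",
                        "AFP", "uE3", "free_bhCG_2", "inhibin_A", "PlGF_2"],
  "correlations": {
    "unaffected": [
      [1.00,  0.00,  0.00,  0.00,  0.00,  0.00,  0.00,  0.00,  0.00],
      [0.00,  1.00,  0.24,  0.25,  0.02,  0.13,  0.19, -0.05,  0.15],
      [0.00,  0.24,  1.00,  0.10,  0.00, -0.05,  0.64,  0.30,  0.08],
      [0.00,  0.25,  0.10,  1.00,  0.05,  0.05,  0.08,  0.05,  0.50],
      [0.00,  0.02,  0.00,  0.05,  1.00,  0.25,  0.06,  0.09,  0.10],
      [0.00,  0.13, -0.05,  0.05,  0.25,  1.00, -0.10, -0.05,  0.10],
      [0.00,  0.19,  0.64,  0.08,  0.06, -0.10,  1.00,  0.42,  0.10],
      [0.00, -0.05,  0.30,  0.05,  0.09, -0.05,  0.42,  1.00,  0.15],
      [0.00,  0.15,  0.08,  0.50,  0.10,  0.10,  0.10,  0.15,  1.00]
    ],
    "affected": [
      [1.00,  0.00,  0.00,  0.00,  0.00,  0.00,  0.00,  0.00,  0.00],
      [0.00,  1.00,  0.19,  0.25,  0.05,  0.18,  0.14,  0.00,  0.15],
      [0.00,  0.19,  1.00,  0.10,  0.00, -0.10,  0.64,  0.15,  0.08],
      [0.00,  0.25,  0.10,  1.00,  0.05,  0.05,  0.08,  0.05,  0.50],
      [0.00,  0.05,  0.00,  0.05,  1.00,  0.16, -0.04,  0.02,  0.10],
      [0.00,  0.18, -0.10,  0.05,  0.16,  1.00, -0.22, -0.11,  0.10],
      [0.00,  0.14,  0.64,  0.08, -0.04, -0.22,  1.00,  0.16,  0.10],
      [0.00,  0.00,  0.15,  0.05,  0.02, -0.11,  0.16,  1.00,  0.15],
      [0.00,  0.15,  0.08,  0.50,  0.10,  0.10,  0.10,  0.15,  1.00]
    ]
  }
}
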