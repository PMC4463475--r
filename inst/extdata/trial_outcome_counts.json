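{
  "description": "Published incidence-screening outcome counts of the UK Collaborative Trial of Ovarian Cancer Screening multimodal arm (annual CA-125 interpreted by the risk-of-ovarian-cancer algorithm). Counts are transcribed from the trial's published screening-flow figure and outcome tables; each block notes what it tallies. iEOC = invasive epithelial ovarian or fallopian-tube cancer; PPC = primary peritoneal cancer.",
  "version": "1.0",
  "counts": {
    "volunteers": 46237,
    "episodes": 296911,
    "incomplete_episodes": 1085,
    "clinical_evaluations": 3329,
    "desk_review_returns": 507,
    "surgeries": 640,
    "laparoscopic_surgeries": 415,
    "benign_or_normal_surgeries": 441,
    "surgical_complications": 20,
    "screen_detected": {
      "iEOC": 133,
      "borderline": 17,
      "nonepithelial": 4,
      "PPC": 12
    },
    "interval": {
      "iEOC": 22,
      "borderline": 9,
      "nonepithelial": 1,
      "PPC": 3
    },
    "roca_flagged_ieoc": 135,
    "cutoff_flagged_ieoc": { "35": 64, "30": 75, "22": 103 },
    "repeat_recommendations": {
      "roca": 29584,
      "cutoff35": 5597,
      "cutoff30": 9699,
      "cutoff22": 28757
    },
    "stage_early_ieoc_detected": 55,
    "type2_ieoc_detected": 109,
    "type1_ieoc_detected": 19,
    "interval_ieoc_low_annual_ca125": 21,
    "median_screen_negative_ca125_u_ml": 13.6
  },
  "printed": {
    "mms_sensitivity_pct": 85.8,
    "mms_sensitivity_ci_pct": [79.3, 90.9],
    "mms_specificity_pct": 99.8,
    "roca_alone_sensitivity_pct": 87.1,
    "cutoff35_sensitivity_pct": 41.3,
    "cutoff30_sensitivity_pct": 48.4,
    "cutoff22_sensitivity_pct": 66.5,
    "ppv_ieoc_pct": 20.8,
    "ppv_with_ppc_pct": 22.7,
    "surgeries_per_ieoc": 4.8,
    "roca_repeat_rate_pct": 10.0,
    "cutoff35_repeat_rate_pct": 1.9,
    "cutoff30_repeat_rate_pct": 3.3,
    "cutoff22_repeat_rate_pct": 9.7,
    "early_stage_fraction_pct": 41.4,
    "type2_fraction_pct": 82.0,
    "complication_rate_pct": 4.5,
    "complication_ci_pct": [2.8, 6.9],
    "auc_roca": 0.915,
    "auc_ca125": 0.869,
    "delong_p": 0.0027
  }
}
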