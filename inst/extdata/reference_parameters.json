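{
  "drug": {
    "ka": 0.59164,
    "F_gut": 0.84,
    "Kp_DAP": 25.52,
    "Kp_re_DAP": 1,
    "Kp_D3G": 1,
    "Km": 479,
    "Vmax_li": 17.988,
    "f_ki_Vmax": 54.78,
    "k_DAPEX_ki": 0.039564,
    "k_D3GEX_ki": 10.646,
    "k_feces": 0.05,
    "ps_re": 0.129522
  },
  "pd": {
    "RTG0": 10,
    "Imax": 0.9,
    "IC50": 20
  },
  "meta": {
    "version": "0.1.0",
    "generator": "scripts/make_reference_parameters.R",
    "calibration_targets": {
      "tmax_h": 2.8,
      "thalf_h": 13,
      "frac_urine_unchanged_pct": 1.3,
      "oral_bioavailability_pct": 78,
      "fed_cmax_reduction_pct": 38,
      "d3g_tmax_h": 5
    },
    "achieved": {
      "tmax_h": 2.9,
      "thalf_h": 12.9748,
      "frac_urine_unchanged_pct": 1.3013,
      "oral_bioavailability_pct": 78.0045,
      "fed_cmax_reduction_pct": 38.1596,
      "d3g_tmax_h": 5.5
    },
    "reference_subject": {
      "BW_kg": 75,
      "renal_class": "normal",
      "hepatic_class": "none",
      "prandial": "fasted",
      "population": "healthy"
    }
  }
}
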