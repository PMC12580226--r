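# Standard scenario grid: one grid per strategy family, one column per
# uptake scenario. Each scenario block is passed to strategy_spec();
# `reference` names the comparator for the ICER row, or
# `reference_mode: same_uptake_fit` compares each colonoscopy scenario
# against FIT-based screening at the same uptake with 70% follow-up.
grids:
  fit_based:
    reference: {kind: FIT_based, fit_uptake: 0.40, tcs_after_fit_uptake: 0.70}
    scenarios:
      - {label: "FIT 40% / follow-up 70%", kind: FIT_based, fit_uptake: 0.40, tcs_after_fit_uptake: 0.70}
      - {label: "FIT 50% / follow-up 70%", kind: FIT_based, fit_uptake: 0.50, tcs_after_fit_uptake: 0.70}
      - {label: "FIT 60% / follow-up 70%", kind: FIT_based, fit_uptake: 0.60, tcs_after_fit_uptake: 0.70}
      - {label: "FIT 80% / follow-up 70%", kind: FIT_based, fit_uptake: 0.80, tcs_after_fit_uptake: 0.70}
      - {label: "FIT 40% / follow-up 90%", kind: FIT_based, fit_uptake: 0.40, tcs_after_fit_uptake: 0.90}
      - {label: "FIT 50% / follow-up 90%", kind: FIT_based, fit_uptake: 0.50, tcs_after_fit_uptake: 0.90}
      - {label: "FIT 60% / follow-up 90%", kind: FIT_based, fit_uptake: 0.60, tcs_after_fit_uptake: 0.90}
      - {label: "FIT 80% / follow-up 90%", kind: FIT_based, fit_uptake: 0.80, tcs_after_fit_uptake: 0.90}
  tcs_based:
    reference_mode: same_uptake_fit
    scenarios:
      - {label: "TCS 10%", kind: TCS_based, primary_tcs_uptake: 0.10}
      - {label: "TCS 20%", kind: TCS_based, primary_tcs_uptake: 0.20}
      - {label: "TCS 40%", kind: TCS_based, primary_tcs_uptake: 0.40}
      - {label: "TCS 50%", kind: TCS_based, primary_tcs_uptake: 0.50}
      - {label: "TCS 60%", kind: TCS_based, primary_tcs_uptake: 0.60}
      - {label: "TCS 80%", kind: TCS_based, primary_tcs_uptake: 0.80}
  combined:
    reference: {kind: FIT_based, fit_uptake: 0.40, tcs_after_fit_uptake: 0.70}
    scenarios:
      - {label: "Combined, TCS arm 20%", kind: Combined, fit_uptake: 0.40, tcs_after_fit_uptake: 0.70, primary_tcs_uptake: 0.20}
      - {label: "Combined, TCS arm 40%", kind: Combined, fit_uptake: 0.40, tcs_after_fit_uptake: 0.70, primary_tcs_uptake: 0.40}
      - {label: "Combined, TCS arm 60%", kind: Combined, fit_uptake: 0.40, tcs_after_fit_uptake: 0.70, primary_tcs_uptake: 0.60}
      - {label: "Combined, TCS arm 80%", kind: Combined, fit_uptake: 0.40, tcs_after_fit_uptake: 0.70, primary_tcs_uptake: 0.80}
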