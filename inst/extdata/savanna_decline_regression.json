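{
  "delta_fire_window_mean": -8.76951810890092,
  "delta_nee_window_mean": -15.7357964149647,
  "delta_gpp_window_mean": 50.3548668813101,
  "indirect_direct_ratio": 1.79437412860727,
  "legacy_nee_1_5": 6.07906305017263,
  "legacy_nee_6_10": 5.06625740742,
  "legacy_nee_11_20": 1.81689611602993,
  "nbe_neutrality_years": 20,
  "fire_annual_mean_period1": 109.827318657521,
  "fire_annual_mean_period2": 106.292787282247
}
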