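# Bundled demonstration scenario: 55 years of daily temperature with a
# planted mean-temperature cue over lag days 81..14 before 20 May.
# Equivalent to phenocue::default_scenario().
years_range: [1961, 2015]
reference_day: "05-20"
climate:
  annual_mean: 9.5
  seasonal_amplitude: 6.5
  seasonal_phase: 200
  warming_trend: 0.03
  ar1_rho: 0.7
  noise_sd: 2.5
phenology:
  mechanism: window
  truth:
    window:
      open: 81
      close: 14
      statistic: mean
      frame: absolute
    intercept: 76
    slope: -6
  noise_sd: 2
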