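[
  { "horizon": "acute", "disorder": "PTSD", "trauma": "moderate", "prevalence": 32.3, "ci_low": 18.2, "ci_high": 50.6 },
  { "horizon": "acute", "disorder": "PTSD", "trauma": "high", "prevalence": 41.3, "ci_low": 28.3, "ci_high": 55.6 },
  { "horizon": "acute", "disorder": "depression", "trauma": "moderate", "prevalence": 34.5, "ci_low": 19.8, "ci_high": 52.9 },
  { "horizon": "acute", "disorder": "depression", "trauma": "high", "prevalence": 37.3, "ci_low": 26.5, "ci_high": 49.6 },
  { "horizon": "three_year", "disorder": "PTSD", "trauma": "moderate", "prevalence": 16.8, "ci_low": 10.7, "ci_high": 25.6 },
  { "horizon": "three_year", "disorder": "PTSD", "trauma": "high", "prevalence": 23.9, "ci_low": 13.5, "ci_high": 38.8 },
  { "horizon": "three_year", "disorder": "depression", "trauma": "moderate", "prevalence": 16.9, "ci_low": 11.2, "ci_high": 24.6 },
  { "horizon": "three_year", "disorder": "depression", "trauma": "high", "prevalence": 37.3, "ci_low": 23.8, "ci_high": 53.2 }
]
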