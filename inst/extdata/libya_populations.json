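[
  { "name": "Misrata", "size": 444812, "trauma_stratum": "moderate", "terror_stratum": "high" },
  { "name": "Benghazi", "size": 674094, "trauma_stratum": "moderate", "terror_stratum": "high" },
  { "name": "Tripoli/Zlitan displaced", "size": 49000, "trauma_stratum": "high", "terror_stratum": "high" },
  { "name": "Misrata displaced", "size": 25000, "trauma_stratum": "high", "terror_stratum": "high" },
  { "name": "Zintan", "size": 40000, "trauma_stratum": "high", "terror_stratum": "high" },
  { "name": "Ras Jdir camps", "size": 3700, "trauma_stratum": "high", "terror_stratum": "high" }
]
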