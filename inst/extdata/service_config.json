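{
  "comment": "Coverage targets are the published planning targets for severe depression (mhGAP-style scale-up model) extended to PTSD-only and comorbid groups; PTSD-only care is restricted to primary healthcare and psychosocial services. Visit rates, bed-day targets, staff:bed ratios and the apportionment matrix are NOT published with the coverage targets; the values below are documented placeholders in the ranges used by LMIC mental-health costing models and should be replaced with setting-specific figures.",
  "coverage_targets": [
    { "service": "long_stay",       "depression_only": 0.005, "ptsd_only": 0.0,  "comorbid": 0.01 },
    { "service": "acute_inpatient", "depression_only": 0.02,  "ptsd_only": 0.0,  "comorbid": 0.04 },
    { "service": "day_care",        "depression_only": 0.01,  "ptsd_only": 0.0,  "comorbid": 0.01 },
    { "service": "outpatient",      "depression_only": 0.20,  "ptsd_only": 0.0,  "comorbid": 0.20 },
    { "service": "primary_care",    "depression_only": 0.30,  "ptsd_only": 0.10, "comorbid": 0.40 },
    { "service": "psychosocial",    "depression_only": 0.20,  "ptsd_only": 0.20, "comorbid": 0.20 }
  ],
  "overall_coverage": { "depression_only": 0.33, "ptsd_only": 0.20, "comorbid": 0.40 },
  "service_parameters": {
    "consultations_per_day": 11,
    "working_days": 225,
    "avg_visits": { "day_care": 50, "outpatient": 3, "primary_care": 3, "psychosocial": 3 },
    "bed_days": { "long_stay": 30, "acute_inpatient": 7 },
    "staff_bed_ratio": { "long_stay": 0.25, "acute_inpatient": 0.35 }
  },
  "apportionment": [
    { "service": "long_stay",       "medical": 0.05, "nurse": 0.60, "psychosocial": 0.35 },
    { "service": "acute_inpatient", "medical": 0.10, "nurse": 0.65, "psychosocial": 0.25 },
    { "service": "day_care",        "medical": 0.05, "nurse": 0.35, "psychosocial": 0.60 },
    { "service": "outpatient",      "medical": 0.30, "nurse": 0.35, "psychosocial": 0.35 },
    { "service": "primary_care",    "medical": 0.25, "nurse": 0.45, "psychosocial": 0.30 },
    { "service": "psychosocial",    "medical": 0.00, "nurse": 0.10, "psychosocial": 0.90 }
  ],
  "workforce_rates": { "medical": 0.18, "nurse": 0.5, "psychosocial": 6.5 }
}
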