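{
  "comment": "Severe-case proportions pooled from World Mental Health Survey disability ratings (Sheehan Disability Scale 7-10 = severe; anxiety disorders proxy PTSD, affective disorders proxy depression) and the comorbidity proportion phi (fraction of PTSD cases also meeting depression criteria).",
  "ptsd": { "prop": 0.30, "ci_low": 0.27, "ci_high": 0.33 },
  "depression": { "prop": 0.53, "ci_low": 0.46, "ci_high": 0.60 },
  "phi": 0.5
}
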