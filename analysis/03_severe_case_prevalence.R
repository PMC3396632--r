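#!/usr/bin/env Rscript
# Step 3: derive severe-case prevalence from the published stratified total
# prevalences and the pooled World Mental Health Survey severity proportions
# (30% of PTSD cases severe, 53% of depression cases), for the acute
# high-political-terror phase and the three-years-post-conflict horizon.

suppressPackageStartupMessages(library(conflictmh))
dir.create("results", showWarnings = FALSE)

sev <- severity_defaults()
out <- do.call(rbind, lapply(c("acute", "three_year"), function(h) {
  total <- published_prevalence_estimates(h)
  res <- total
  for (i in seq_len(nrow(res))) {
    s <- if (res$disorder[i] == "PTSD") sev$ptsd$prop else sev$depression$prop
    res[i, c("prevalence", "ci_low", "ci_high")] <-
      severe_prevalence(res[i, ], s, percent = TRUE)
  }
  cbind(horizon = h, res)
}))

cat("severe-case prevalence (%, 95% CI):\n")
print(out, row.names = FALSE)
write.csv(out, "results/severe_prevalence.csv", row.names = FALSE)
cat("wrote results/severe_prevalence.csv\n")
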