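#!/usr/bin/env Rscript
# Step 1: simulate a study-level survey table under the data-generating
# process the meta-regression assumes: logit(p_i) = b0 + b1 * high_trauma_i
# + u_i, u_i ~ N(0, tau2), cases_i ~ Binomial(n_i, p_i). The truth columns
# are kept so later steps can measure recovery.

suppressPackageStartupMessages(library(conflictmh))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(
  n_studies = 200,
  beta = c(intercept = -1.0, high_trauma = 0.8),
  tau2 = 0.3,
  outcome = "PTSD",
  seed = 20260901
)
tab <- generate_study_table(cfg)

write_study_table(tab, "results/synthetic_studies.csv")

ratio <- pte_adversity_ratio(tab$pte_endorsed, tab$pte_assessed)
strata <- stratify_exposure(tab$pts, ratio)
cat(sprintf("simulated %d surveys (median n = %d)\n", nrow(tab), median(tab$n)))
cat(sprintf("high-trauma stratum share: %.2f\n", mean(strata$trauma == "high")))
cat(sprintf("raw prevalence range: %.3f - %.3f\n",
            min(tab$cases / tab$n), max(tab$cases / tab$n)))
cat("wrote results/synthetic_studies.csv\n")
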