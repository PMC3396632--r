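#!/usr/bin/env Rscript
# Step 5: service coverage and staffing. Patients accessing each service
# over one year from the coverage targets, clinician FTE from the staffing
# algorithm (11 consultations/day, 225 working days), and the workforce gap
# against WHO per-100,000 availability rates for the combined 1,236,606
# population.

suppressPackageStartupMessages(library(conflictmh))
dir.create("results", showWarnings = FALSE)

r <- run_pipeline("paper_reproduction", horizon = "acute")

cat("patients accessing services over 1 year:\n")
print(r$service_use, row.names = FALSE)

cat("\nheadline treatment targets (overall coverage, rounded to 1,000):\n")
print(unlist(r$treatment_targets))

cat("\nFTE staffing requirement by population (placeholder visit/apportionment config):\n")
print(r$staffing$per_population, row.names = FALSE)
cat(sprintf("\ncombined requirement: %.0f FTE (%s)\n",
            r$staffing$combined$total_fte,
            paste(names(r$staffing$combined$staff),
                  r$staffing$combined$staff, sep = "=", collapse = ", ")))

cat("\nworkforce gap vs WHO availability rates:\n")
print(r$workforce, row.names = FALSE)

write.csv(r$service_use, "results/service_use.csv", row.names = FALSE)
write.csv(r$staffing$per_population, "results/staffing_by_population.csv", row.names = FALSE)
write.csv(r$workforce, "results/workforce_gap.csv", row.names = FALSE)
cat("wrote results/service_use.csv, results/staffing_by_population.csv, results/workforce_gap.csv\n")
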