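#!/usr/bin/env Rscript
# Build the contrast-specific analysis sets: exclusions, allele grouping,
# standardization, score rescaling.

library(betacog)
cohort <- read_cohort("results/cohort.csv")

for (contrast in c("e2_vs_e3", "e4_vs_e3", "all_three")) {
  aset <- make_analysis_set(cohort, contrast)
  out <- file.path("results", paste0("analysis_set_", contrast, ".csv"))
  write_analysis_set(aset, out)
  cat(sprintf("%s: %d rows, %d participants; age mean %.1f (sd %.1f), edu mean %.1f (sd %.1f)\n",
              contrast, nrow(aset$rows),
              length(unique(aset$rows$participant_id)),
              aset$scaling$age_mean, aset$scaling$age_sd,
              aset$scaling$edu_mean, aset$scaling$edu_sd))
}
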