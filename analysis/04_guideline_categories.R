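#!/usr/bin/env Rscript
# Assign every eligible patient a pre-test probability category under the
# ASGE 2010, ASGE 2019, and ESGE 2019 criteria and tabulate category
# membership against the stone findings at endoscopy.

library(cdltrend)
data_dir <- "results/data"
eligible <- read_cohort(file.path(data_dir, "patients_eligible.tsv"),
                        file.path(data_dir, "labs_eligible.tsv"))

assignments <- classify_guidelines(eligible)
readr::write_csv(assignments, "results/assignments.csv")

tab <- dplyr::count(
  dplyr::left_join(assignments,
                   dplyr::select(eligible$patients, "id", "cdl_found"), by = "id"),
  .data$guideline, .data$category, .data$cdl_found)
readr::write_csv(tab, "results/category_by_outcome.csv")

cat("Category membership by guideline (stone-positive / total):\n")
for (gl in unique(tab$guideline)) {
  for (cat_ in c("high", "intermediate", "low")) {
    sub <- tab[tab$guideline == gl & tab$category == cat_, ]
    cat(sprintf("  %-9s %-13s %d/%d\n", gl, cat_,
                sum(sub$n[sub$cdl_found]), sum(sub$n)))
  }
}
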