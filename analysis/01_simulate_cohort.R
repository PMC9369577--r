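#!/usr/bin/env Rscript
# Simulate the synthetic in-patient cohort that stands in for the (unshared)
# endoscopy registry: 952 adults referred for suspected bile-duct stones,
# with latent retained/passed/no-stone states, log-normal enzyme
# trajectories over the 72 h before the procedure, and the registry's
# per-offset lab availability. A small fraction of records is then spoiled
# with the disqualifiers the eligibility stage must catch.

library(cdltrend)
seed <- 20260101
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

set.seed(seed)
gen <- generate_cohort(generator_params(n_patients = 952), seed = seed)
cohort <- gen$cohort

# spoil ~4% of records the way registry review would find them:
# unsuccessful cannulation, a repeat procedure within 14 days
n <- nrow(cohort$patients)
spoil <- sample(n, 40)
cohort$patients$successful[spoil[1:25]] <- FALSE
cohort$patients$days_since_prior_procedure[spoil[26:40]] <- sample(1:14, 15, TRUE)

write_cohort(cohort, file.path(out, "patients.tsv"), file.path(out, "labs.tsv"))
readr::write_tsv(gen$truth, file.path(out, "truth.tsv"))

cat(sprintf("Simulated %d patients (%d lab draws) with seed %d\n",
            n, nrow(cohort$labs), seed))
cat(sprintf("Latent states: %s\n",
            paste(sprintf("%s=%d", names(table(gen$truth$state)),
                          table(gen$truth$state)), collapse = ", ")))
cat(sprintf("Stone prevalence at endoscopy: %.1f%%\n",
            100 * mean(cohort$patients$cdl_found)))
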