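#!/usr/bin/env Rscript
# Evaluate every index test: enzyme increases against the presence of duct
# stones, enzyme decreases against their absence, and guideline high /
# intermediate categories against the stone findings — each as a full
# accuracy / sensitivity / specificity / PPV / NPV panel with 95% CIs.

library(cdltrend)
data_dir <- "results/data"
eligible <- read_cohort(file.path(data_dir, "patients_eligible.tsv"),
                        file.path(data_dir, "labs_eligible.tsv"))
cfg <- trend_config()

inc <- trend_performance_table(eligible, "increase", cfg)
dec <- trend_performance_table(eligible, "decrease", cfg)
gl <- dplyr::bind_rows(lapply(c("ASGE2010", "ASGE2019", "ESGE2019"),
                              function(g) guideline_performance(eligible, g)))
readr::write_csv(format_performance(inc), "results/table_increase.csv")
readr::write_csv(format_performance(dec), "results/table_decrease.csv")
readr::write_csv(format_performance(gl), "results/table_guidelines.csv")

cat("Enzyme increases predicting the PRESENCE of stones:\n")
print(as.data.frame(format_performance(inc)[, c("predictor", "specificity", "ppv", "n_model")]))
cat("\nEnzyme decreases predicting the ABSENCE of stones:\n")
print(as.data.frame(format_performance(dec)[, c("predictor", "specificity", "npv", "n_model")]))
cat("\nGuideline categories (stone yield and panel):\n")
print(as.data.frame(format_performance(gl)[, c("guideline", "category", "cdl_in_category",
                                               "n_category", "sensitivity", "ppv")]))
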