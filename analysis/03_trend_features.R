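#!/usr/bin/env Rscript
# Compute the dynamic liver-enzyme trend features on the eligible cohort:
# the maximal relative rise and fall of total bilirubin, ALT, and ALP over
# the 72 h window, the 30%/50% threshold flags used as index tests, and the
# per-outcome-group percent-change distributions.

library(cdltrend)
data_dir <- "results/data"
eligible <- read_cohort(file.path(data_dir, "patients_eligible.tsv"),
                        file.path(data_dir, "labs_eligible.tsv"))
cfg <- trend_config()

feats <- trend_features(eligible, cfg)
flags <- predictor_flags(feats, cfg$thresholds)
readr::write_csv(feats, "results/trend_features.csv")
readr::write_csv(flags, "results/predictor_flags.csv")

defined <- tapply(!is.na(feats$max_rel_increase), feats$analyte, sum)
cat("Patients with a defined trend (>= 2 usable in-window values):\n")
print(defined)

for (a in cfg$analytes) {
  d <- percent_change_distribution(eligible, a, cfg)
  readr::write_csv(d$samples, sprintf("results/percent_change_%s.csv", a))
  if (!is.null(d$density)) {
    readr::write_csv(d$density, sprintf("results/density_%s.csv", a))
  }
  cat(sprintf("%s: median signed change %+.0f%% with stones, %+.0f%% without\n",
              a,
              100 * median(d$samples$change[d$samples$cdl]),
              100 * median(d$samples$change[!d$samples$cdl])))
}
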