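Package: cdltrend
Title: Dynamic Liver-Enzyme Trends and Guideline Risk Stratification for
    Suspected Choledocholithiasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate dynamic liver-enzyme trends as bedside
    predictors of choledocholithiasis in in-patients awaiting ERCP or EUS.
    Computes maximal relative increases and decreases of total bilirubin,
    ALT, and ALP over a configurable pre-procedure window, assigns
    ASGE 2010, ASGE 2019, and ESGE 2019 pre-test probability categories,
    and reports full diagnostic test performance (accuracy, sensitivity,
    specificity, PPV, NPV) with exact and approximate binomial confidence
    intervals. Includes a synthetic in-patient cohort generator with latent
    retained/passed/absent stone states, log-normal laboratory
    trajectories, and per-draw missingness, so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
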