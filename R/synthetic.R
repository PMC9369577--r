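#' Parameters for the synthetic in-patient cohort generator
#'
#' The generator emulates the statistical structure the trend analysis
#' assumes: a latent stone state per patient (`retained` — stone present at
#' endoscopy; `passed` — stone migrated out while awaiting the procedure;
#' `never` — no stone), log-normal enzyme baselines matched by moments to
#' the published cohort's group means/SDs, multiplicative drift (retained)
#' or decay after a uniformly-drawn passage time (passed), log-normal
#' measurement noise, and independent per-draw missingness at the four
#' scheduled offsets (-72, -48, -24, 0 h) with the cohort's observed
#' availability rates. Labs at an offset are drawn as a grouped panel: one
#' availability draw per patient-offset covers all analytes, matching how
#' liver panels are ordered. Imaging findings and demographics follow the
#' published group-conditional rates. AST and GGT baselines are not
#' calibrated to any published distribution (none is available) and are
#' plausible round numbers only.
#'
#' @param n_patients Cohort size.
#' @param prevalence P(stone found at endoscopy) (default 0.708).
#' @param passed_fraction_of_negatives Fraction of stone-negative patients
#'   whose negativity is due to a recently passed stone (default 0.3).
#' @param baselines Named list `positive`/`negative`, each a data frame with
#'   `analyte`, `mean`, `sd` (arithmetic moments of the log-normal
#'   baseline; bilirubin in umol/L, enzymes in U/L).
#' @param retained_drift_per_day Multiplicative daily rise while a stone is
#'   retained (>= 1; default 1.15).
#' @param passed_decay_per_day Multiplicative daily fall after stone
#'   passage (<= 1; default 0.55, i.e. enzymes roughly halve each day).
#' @param measurement_cv Coefficient of variation of the multiplicative
#'   measurement noise (default 0.15).
#' @param schedule_offsets,schedule_probs Draw times (hours, <= 0) and the
#'   per-offset probability that the panel was drawn (defaults 195/878,
#'   358/878, 565/878, 538/878 at -72/-48/-24/0 h).
#' @param p_stone_on_imaging_given_cdl P(stone or sludge seen on US | stone
#'   retained) (default 0.547); never seen when no stone is retained.
#' @param p_stone_ct_given_cdl P(stone on cross-sectional imaging | stone
#'   retained); not calibrated (default 0.15).
#' @param p_cbd_gt6_given_cdl,p_cbd_gt6_given_no_cdl P(CBD > 6 mm) by group
#'   (defaults 0.553 / 0.479).
#' @param cbd_dilated_mean_sd Named list `positive`/`negative` of
#'   `c(mean, sd)` for CBD size among dilated ducts, mm (defaults
#'   12.4/4.5 and 11.6/3.8, truncated above 6).
#' @param age_mean_sd Named list `positive`/`negative` of `c(mean, sd)`
#'   (defaults 59.3/21.2 and 66.0/18.2, truncated at 18).
#' @param p_female P(female) (default 0.586).
#' @param p_ercp_given_cdl,p_ercp_given_no_cdl P(procedure is ERCP rather
#'   than EUS) by group (defaults 0.977 / 0.860).
#' @param p_gallstone_pancreatitis P(clinical gallstone pancreatitis); not
#'   calibrated (default 0.10).
#' @return A validated `generator_params` list.
#' @export
generator_params <- function(
    n_patients = 878,
    prevalence = 0.708,
    passed_fraction_of_negatives = 0.3,
    baselines = default_baselines(),
    retained_drift_per_day = 1.15,
    passed_decay_per_day = 0.55,
    measurement_cv = 0.15,
    schedule_offsets = c(-72, -48, -24, 0),
    schedule_probs = c(195, 358, 565, 538) / 878,
    p_stone_on_imaging_given_cdl = 0.547,
    p_stone_ct_given_cdl = 0.15,
    p_cbd_gt6_given_cdl = 0.553,
    p_cbd_gt6_given_no_cdl = 0.479,
    cbd_dilated_mean_sd = list(positive = c(12.4, 4.5), negative = c(11.6, 3.8)),
    age_mean_sd = list(positive = c(59.3, 21.2), negative = c(66.0, 18.2)),
    p_female = 0.586,
    p_ercp_given_cdl = 0.977,
    p_ercp_given_no_cdl = 0.860,
    p_gallstone_pancreatitis = 0.10) {
  p <- as.list(environment())
  probs <- c(p$prevalence, p$passed_fraction_of_negatives, p$schedule_probs,
             p$p_stone_on_imaging_given_cdl, p$p_stone_ct_given_cdl,
             p$p_cbd_gt6_given_cdl, p$p_cbd_gt6_given_no_cdl, p$p_female,
             p$p_ercp_given_cdl, p$p_ercp_given_no_cdl, p$p_gallstone_pancreatitis)
  .assert(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  .assert(p$n_patients >= 0, "n_patients must be non-negative")
  .assert(p$retained_drift_per_day >= 1, "retained drift must be >= 1 per day")
  .assert(p$passed_decay_per_day <= 1 && p$passed_decay_per_day > 0,
          "passed decay must lie in (0, 1]")
  .assert(p$measurement_cv >= 0, "measurement_cv must be non-negative")
  .assert(all(p$schedule_offsets <= 0), "schedule offsets are pre-procedure (<= 0)")
  .assert(length(p$schedule_offsets) == length(p$schedule_probs),
          "schedule offsets/probs length mismatch")
  structure(p, class = "generator_params")
}

#' Default baseline moments by outcome group
#'
#' Total bilirubin, ALT, and ALP moments match the published cohort's group
#' means and SDs; AST and GGT are uncalibrated placeholders.
#'
#' @return Named list of `positive`/`negative` data frames.
#' @export
default_baselines <- function() {
  list(
    positive = data.frame(
      analyte = c("TBILI", "ALT", "ALP", "AST", "GGT"),
      mean = c(64.9, 292.4, 278.2, 250, 320),
      sd = c(62.1, 346.6, 256.5, 280, 280)),
    negative = data.frame(
      analyte = c("TBILI", "ALT", "ALP", "AST", "GGT"),
      mean = c(60.6, 283.6, 261.1, 240, 300),
      sd = c(63.3, 267.0, 191.4, 230, 250)))
}

# moment-matched log-normal parameters from arithmetic mean/sd
.lnorm_params <- function(mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

.noise_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Expected laboratory trajectory value (noise-free)
#'
#' Retained stones drive a multiplicative daily rise from the window start;
#' passed stones decay from the (patient-specific) passage time; patients
#' who never had a stone fluctuate around their baseline. Measurement noise
#' multiplies this mean structure.
#'
#' @param state `"retained"`, `"passed"`, or `"never"`.
#' @param baseline Baseline concentration (> 0), anchored at the window
#'   start.
#' @param offsets Hours relative to the procedure (<= 0).
#' @param params A [generator_params()].
#' @param passage_time Hours (<= 0) at which a passed stone cleared; only
#'   used for `state = "passed"`.
#' @return Numeric vector of expected values at `offsets`.
#' @export
trajectory_mean <- function(state, baseline, offsets, params, passage_time = NULL) {
  .assert(baseline > 0, "baseline must be positive")
  .assert(all(offsets <= 0), "offsets must be pre-procedure (<= 0)")
  window_start <- min(params$schedule_offsets)
  switch(state,
    retained = baseline * params$retained_drift_per_day^((offsets - window_start) / 24),
    passed = {
      .assert(!is.null(passage_time), "passed trajectories need a passage_time")
      baseline * params$passed_decay_per_day^(pmax(0, offsets - passage_time) / 24)
    },
    never = rep(baseline, length(offsets)),
    stop("unknown latent state '", state, "'"))
}

#' One noisy trajectory draw
#'
#' @inheritParams trajectory_mean
#' @return Numeric vector of simulated values at `offsets`.
#' @export
trajectory <- function(state, baseline, offsets, params, passage_time = NULL) {
  trajectory_mean(state, baseline, offsets, params, passage_time) *
    .noise_factor(length(offsets), params$measurement_cv)
}

#' Generate a synthetic cohort
#'
#' Reproducible given `seed`: a single RNG stream is consumed in patient-id
#' order. The returned truth table records each patient's latent state;
#' `cdl_found` is `TRUE` exactly for `retained` patients, and a stone is
#' never seen on imaging in stone-negative patients.
#'
#' @param params A [generator_params()].
#' @param seed Integer seed.
#' @return List: `cohort` (a `cdl_cohort`) and `truth` (tibble `id`,
#'   `state`).
#' @export
generate_cohort <- function(params = generator_params(), seed) {
  .assert(inherits(params, "generator_params"), "params must come from generator_params()")
  .assert(!missing(seed), "seed is mandatory")
  set.seed(as.integer(seed))
  n <- params$n_patients
  ids <- sprintf("S%05d", seq_len(n))
  if (n == 0) {
    empty_p <- tibble::as_tibble(stats::setNames(
      rep(list(logical(0)), length(patient_columns())), patient_columns()))
    empty_l <- tibble::tibble(id = character(0), analyte = character(0),
                              t_hours = numeric(0), value = numeric(0),
                              unit = character(0))
    return(list(cohort = new_cohort(empty_p, empty_l),
                truth = tibble::tibble(id = character(0), state = character(0))))
  }

  cdl <- stats::runif(n) < params$prevalence
  passed <- !cdl & stats::runif(n) < params$passed_fraction_of_negatives
  state <- ifelse(cdl, "retained", ifelse(passed, "passed", "never"))
  grp <- ifelse(cdl, "positive", "negative")

  rtrunc_norm <- function(n, mean, sd, lower) {
    u <- stats::runif(n, stats::pnorm(lower, mean, sd), 1)
    stats::qnorm(u, mean, sd)
  }
  age <- numeric(n)
  for (g in c("positive", "negative")) {
    idx <- grp == g
    ms <- params$age_mean_sd[[g]]
    age[idx] <- rtrunc_norm(sum(idx), ms[1], ms[2], 18)
  }
  sex <- ifelse(stats::runif(n) < params$p_female, "F", "M")
  proc_type <- ifelse(stats::runif(n) < ifelse(cdl, params$p_ercp_given_cdl,
                                               params$p_ercp_given_no_cdl),
                      "ERCP", "EUS")
  pancreatitis <- stats::runif(n) < params$p_gallstone_pancreatitis

  stone_us <- cdl & stats::runif(n) < params$p_stone_on_imaging_given_cdl
  stone_ct <- cdl & stats::runif(n) < params$p_stone_ct_given_cdl
  dilated <- stats::runif(n) < ifelse(cdl, params$p_cbd_gt6_given_cdl,
                                      params$p_cbd_gt6_given_no_cdl)
  cbd <- stats::runif(n, 2, 6)
  for (g in c("positive", "negative")) {
    idx <- grp == g & dilated
    ms <- params$cbd_dilated_mean_sd[[g]]
    cbd[idx] <- rtrunc_norm(sum(idx), ms[1], ms[2], 6)
  }

  patients <- tibble::tibble(
    id = ids, age = age, sex = sex,
    inpatient = TRUE, cholangitis = FALSE, gallstone_pancreatitis = pancreatitis,
    prior_cholecystectomy = FALSE, prior_sphincterotomy = FALSE,
    biliary_stent = FALSE, indication_suspected_cdl = TRUE,
    stone_on_us = stone_us, stone_on_ct_mri = stone_ct,
    cbd_mm = round(cbd, 1),
    imaging_days_before = sample.int(10, n, replace = TRUE) - 1L,
    proc_type = proc_type, successful = TRUE, cdl_found = cdl,
    days_since_prior_procedure = NA_integer_)

  offsets <- params$schedule_offsets
  drawn <- matrix(stats::runif(n * length(offsets)), n) <
    matrix(params$schedule_probs, n, length(offsets), byrow = TRUE)
  passage <- stats::runif(n, min(offsets), 0)

  analytes <- params$baselines$positive$analyte
  lab_blocks <- lapply(analytes, function(a) {
    baseline <- numeric(n)
    for (g in c("positive", "negative")) {
      idx <- grp == g
      b <- params$baselines[[g]]
      lp <- .lnorm_params(b$mean[b$analyte == a], b$sd[b$analyte == a])
      baseline[idx] <- stats::rlnorm(sum(idx), lp$meanlog, lp$sdlog)
    }
    # n x offsets matrix of noise-free means, then noise, then missingness
    window_start <- min(offsets)
    mean_mat <- matrix(0, n, length(offsets))
    for (j in seq_along(offsets)) {
      t <- offsets[j]
      mean_mat[, j] <- ifelse(
        state == "retained",
        baseline * params$retained_drift_per_day^((t - window_start) / 24),
        ifelse(state == "passed",
               baseline * params$passed_decay_per_day^(pmax(0, t - passage) / 24),
               baseline))
    }
    values <- mean_mat * matrix(.noise_factor(n * length(offsets),
                                              params$measurement_cv), n)
    keep <- which(drawn, arr.ind = TRUE)
    tibble::tibble(id = ids[keep[, 1]], analyte = a,
                   t_hours = offsets[keep[, 2]],
                   value = round(values[keep], 1),
                   unit = .analyte_units[[a]][1])
  })
  labs <- dplyr::bind_rows(lab_blocks)
  list(cohort = new_cohort(patients, labs),
       truth = tibble::tibble(id = ids, state = state))
}
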