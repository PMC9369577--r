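#' Run the full triage analysis pipeline
#'
#' Simulate (or read) a cohort, apply the eligibility flow, compute trend
#' features and threshold flags, assign guideline risk categories, and
#' evaluate every predictor and guideline category, writing the report
#' bundle to `out_dir`: `flow.json`, `trends.csv`, `assignments.csv`,
#' `table_increase.csv` / `table_decrease.csv` (trend-predictor
#' performance), `table_guidelines.csv`, `density_<analyte>.csv`, the
#' simulated input tables when a generator is used, and `run_log.txt`
#' (package version, configuration hash, seed). Any stage failure aborts
#' with the stage name and cause. Given a seed, the whole bundle is a pure
#' function of the configuration.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; mandatory when simulating.
#' @param params A [generator_params()], to simulate the cohort; mutually
#'   exclusive with `patient_path`/`lab_path`.
#' @param patient_path,lab_path Delimited cohort files to read instead.
#' @param schema A [cohort_schema()] for reading.
#' @param trend A [trend_config()].
#' @param ranges A [reference_ranges()].
#' @param rules Eligibility rules, see [eligibility_rules()].
#' @param predictor_ci,guideline_ci CI methods for the trend and guideline
#'   tables.
#' @param alpha CI error rate.
#' @return Invisibly, a list with the in-memory results (`flow`, `trends`,
#'   `flags`, `assignments`, `table_increase`, `table_decrease`,
#'   `table_guidelines`, `densities`).
#' @export
run_pipeline <- function(out_dir, seed = NULL, params = NULL,
                         patient_path = NULL, lab_path = NULL,
                         schema = cohort_schema(), trend = trend_config(),
                         ranges = reference_ranges(), rules = eligibility_rules(),
                         predictor_ci = "clopper_pearson", guideline_ci = "wald",
                         alpha = 0.05) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  sim <- !is.null(params)
  .assert(xor(sim, !is.null(patient_path) && !is.null(lab_path)),
          "provide either generator params or both cohort file paths")
  cohort <- if (sim) {
    stage("simulate", {
      .assert(!is.null(seed), "simulation requires a seed")
      gen <- generate_cohort(params, seed)
      write_cohort(gen$cohort, file.path(out_dir, "patients.tsv"),
                   file.path(out_dir, "labs.tsv"))
      readr::write_tsv(gen$truth, file.path(out_dir, "truth.tsv"))
      gen$cohort
    })
  } else {
    stage("read", read_cohort(patient_path, lab_path, schema))
  }

  flow <- stage("filter", {
    res <- apply_eligibility(cohort, rules)
    writeLines(flow_summary(res, file.path(out_dir, "flow.json")),
               file.path(out_dir, "flow.txt"))
    res
  })
  eligible <- flow$eligible

  feats <- stage("trends", trend_features(eligible, trend))
  flags <- stage("trends", predictor_flags(feats, trend$thresholds))
  stage("trends", {
    readr::write_csv(dplyr::left_join(
      tidyr::pivot_wider(feats, names_from = "analyte",
                         values_from = c("n_measurements", "max_rel_increase",
                                         "max_rel_decrease")),
      flags, by = "id"), file.path(out_dir, "trends.csv"))
  })

  assignments <- stage("classify", classify_guidelines(eligible, ranges))
  readr::write_csv(assignments, file.path(out_dir, "assignments.csv"))

  t_inc <- stage("evaluate", trend_performance_table(eligible, "increase", trend,
                                                     predictor_ci, alpha))
  t_dec <- stage("evaluate", trend_performance_table(eligible, "decrease", trend,
                                                     predictor_ci, alpha))
  t_gl <- stage("evaluate", dplyr::bind_rows(lapply(
    c("ASGE2010", "ASGE2019", "ESGE2019"),
    function(gl) guideline_performance(eligible, gl, ranges, guideline_ci, alpha))))
  readr::write_csv(format_performance(t_inc), file.path(out_dir, "table_increase.csv"))
  readr::write_csv(format_performance(t_dec), file.path(out_dir, "table_decrease.csv"))
  readr::write_csv(format_performance(t_gl), file.path(out_dir, "table_guidelines.csv"))

  densities <- stage("density", {
    out <- list()
    for (a in trend$analytes) {
      d <- suppressWarnings(percent_change_distribution(eligible, a, trend))
      out[[a]] <- d
      if (!is.null(d$density)) {
        readr::write_csv(d$density, file.path(out_dir, paste0("density_", a, ".csv")))
      }
    }
    out
  })

  cfg <- list(seed = seed, sim = sim, trend = unclass(trend),
              ranges = unclass(ranges), rules = rules,
              predictor_ci = predictor_ci, guideline_ci = guideline_ci,
              alpha = alpha, params = if (sim) unclass(params))
  writeLines(c(
    sprintf("cdltrend %s", as.character(utils::packageVersion("cdltrend"))),
    sprintf("seed: %s", if (is.null(seed)) "none" else seed),
    sprintf("config sha: %s", rlang::hash(cfg))),
    file.path(out_dir, "run_log.txt"))

  invisible(list(flow = flow, trends = feats, flags = flags,
                 assignments = assignments, table_increase = t_inc,
                 table_decrease = t_dec, table_guidelines = t_gl,
                 densities = densities))
}
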