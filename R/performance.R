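#' Confusion counts for a binary index test
#'
#' Patients whose flag is unknown are dropped listwise (no imputation), so
#' the modelled n varies by predictor. The condition being predicted can be
#' the *presence* of duct stones (`target = "presence"`) or — as for the
#' enzyme-decrease predictors — their *absence* (`target = "absence"`, where
#' condition-positive means no stone was found).
#'
#' @param flags Logical vector (NA = unknown), optionally named by patient id.
#' @param outcomes Logical vector of confirmed stone findings, named the
#'   same way when `flags` is named.
#' @param target `"presence"` or `"absence"`.
#' @return List: `tp`, `fp`, `fn`, `tn`, `n_model`.
#' @export
build_confusion <- function(flags, outcomes, target = c("presence", "absence")) {
  target <- match.arg(target)
  if (!is.null(names(flags)) || !is.null(names(outcomes))) {
    .assert(!is.null(names(flags)) && !is.null(names(outcomes)),
            "either both or neither of flags/outcomes may be named")
    .assert(setequal(names(flags), names(outcomes)),
            "flags and outcomes are keyed by different patient ids")
    outcomes <- outcomes[names(flags)]
  } else {
    .assert(length(flags) == length(outcomes), "flags and outcomes differ in length")
  }
  keep <- !is.na(flags) & !is.na(outcomes)
  flags <- flags[keep]
  cond <- if (target == "presence") outcomes[keep] else !outcomes[keep]
  list(tp = sum(flags & cond), fp = sum(flags & !cond),
       fn = sum(!flags & cond), tn = sum(!flags & !cond),
       n_model = sum(keep))
}

#' Exact and approximate binomial confidence intervals
#'
#' `clopper_pearson` gives the exact interval from beta quantiles (lower
#' bound exactly 0 when `x = 0`, upper exactly 1 when `x = n`); `wald` the
#' normal approximation clipped to `[0, 1]`; `wilson` the score interval.
#'
#' @param x Successes (`0 <= x <= n`).
#' @param n Trials; `n = 0` returns `c(NA, NA)` (not reportable).
#' @param method One of `"clopper_pearson"`, `"wald"`, `"wilson"`.
#' @param alpha Two-sided error rate (default 0.05).
#' @return `c(lower, upper)` as proportions.
#' @export
binom_ci <- function(x, n, method = c("clopper_pearson", "wald", "wilson"),
                     alpha = 0.05) {
  method <- match.arg(method)
  .assert(n >= 0 && x >= 0 && x <= n, "need 0 <= x <= n")
  if (n == 0) return(c(NA_real_, NA_real_))
  p <- x / n
  switch(method,
    clopper_pearson = c(
      if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1),
      if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)),
    wald = {
      z <- stats::qnorm(1 - alpha / 2)
      half <- z * sqrt(p * (1 - p) / n)
      c(max(0, p - half), min(1, p + half))
    },
    wilson = {
      z <- stats::qnorm(1 - alpha / 2)
      denom <- 1 + z^2 / n
      centre <- (p + z^2 / (2 * n)) / denom
      half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
      c(centre - half, centre + half)
    })
}

#' One performance metric from a 2x2 table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)`,
#' NPV `tn/(tn+fn)`, accuracy `(tp+tn)/n`, each with a binomial CI on its
#' own denominator. A zero denominator makes the estimate not reportable
#' (`NA` point and bounds), as happens for PPV when the positive event rate
#' is nil.
#'
#' @param tbl List with `tp`, `fp`, `fn`, `tn` (e.g. from
#'   [build_confusion()]).
#' @param which Metric name.
#' @param method,alpha Passed to [binom_ci()].
#' @return One-row tibble: `metric`, `numerator`, `denominator`, `point`,
#'   `ci_lower`, `ci_upper` (percentages), `method`, `n_model`.
#' @export
metric <- function(tbl, which = c("accuracy", "sensitivity", "specificity", "ppv", "npv"),
                   method = "clopper_pearson", alpha = 0.05) {
  which <- match.arg(which)
  n_model <- tbl$tp + tbl$fp + tbl$fn + tbl$tn
  num_den <- switch(which,
    sensitivity = c(tbl$tp, tbl$tp + tbl$fn),
    specificity = c(tbl$tn, tbl$tn + tbl$fp),
    ppv = c(tbl$tp, tbl$tp + tbl$fp),
    npv = c(tbl$tn, tbl$tn + tbl$fn),
    accuracy = c(tbl$tp + tbl$tn, n_model))
  x <- num_den[1]
  n <- num_den[2]
  if (n == 0) {
    point <- NA_real_
    ci <- c(NA_real_, NA_real_)
  } else {
    point <- 100 * x / n
    ci <- 100 * binom_ci(x, n, method, alpha)
  }
  tibble::tibble(metric = which, numerator = x, denominator = n, point = point,
                 ci_lower = ci[1], ci_upper = ci[2], method = method,
                 n_model = n_model)
}

#' Full metric panel for a 2x2 table
#'
#' @inheritParams metric
#' @return Five-row tibble (accuracy, sensitivity, specificity, PPV, NPV).
#' @export
metric_panel <- function(tbl, method = "clopper_pearson", alpha = 0.05) {
  dplyr::bind_rows(lapply(c("accuracy", "sensitivity", "specificity", "ppv", "npv"),
                          function(w) metric(tbl, w, method, alpha)))
}

.panel_row <- function(tbl, method, alpha) {
  panel <- metric_panel(tbl, method, alpha)
  wide <- list(n_model = panel$n_model[1])
  for (i in seq_len(nrow(panel))) {
    m <- panel$metric[i]
    wide[[m]] <- panel$point[i]
    wide[[paste0(m, "_lo")]] <- panel$ci_lower[i]
    wide[[paste0(m, "_hi")]] <- panel$ci_upper[i]
  }
  tibble::as_tibble(wide)
}

#' Performance of one trend predictor
#'
#' Computes trend features and flags for the cohort, builds the confusion
#' table against confirmed duct stones (oriented to the presence or the
#' absence of stones), and reports the five-metric panel.
#'
#' @param cohort An eligible `cdl_cohort`.
#' @param predictor_id E.g. `"ALP_dec_50"` (see [predictor_ids()]).
#' @param target `"presence"` or `"absence"`.
#' @param config A [trend_config()].
#' @param method,alpha CI method and level.
#' @param flags Optional precomputed [predictor_flags()] table (saves
#'   recomputation when evaluating many predictors).
#' @return One-row tibble: `predictor`, `target`, `n_model`, and
#'   `point`/`lo`/`hi` columns for each metric, percentages at full
#'   precision.
#' @export
evaluate_predictor <- function(cohort, predictor_id, target = c("presence", "absence"),
                               config = trend_config(), method = "clopper_pearson",
                               alpha = 0.05, flags = NULL) {
  target <- match.arg(target)
  if (is.null(flags)) {
    flags <- predictor_flags(trend_features(cohort, config), config$thresholds)
  }
  .assert(predictor_id %in% names(flags), "unknown predictor '%s'", predictor_id)
  f <- stats::setNames(flags[[predictor_id]], flags$id)
  o <- stats::setNames(cohort$patients$cdl_found, cohort$patients$id)
  tbl <- build_confusion(f, o, target)
  dplyr::bind_cols(tibble::tibble(predictor = predictor_id, target = target),
                   .panel_row(tbl, method, alpha))
}

#' Performance table for all trend predictors in one direction
#'
#' One row per predictor family and threshold; increases are evaluated
#' against the presence of stones and decreases against their absence,
#' mirroring how rising and falling enzymes are used clinically.
#'
#' @param cohort An eligible `cdl_cohort`.
#' @param direction `"increase"` or `"decrease"`.
#' @param config,method,alpha See [evaluate_predictor()].
#' @return Tibble with 6 families x `length(thresholds)` rows.
#' @export
trend_performance_table <- function(cohort, direction = c("increase", "decrease"),
                                    config = trend_config(),
                                    method = "clopper_pearson", alpha = 0.05) {
  direction <- match.arg(direction)
  dir <- substr(direction, 1, 3)
  target <- if (direction == "increase") "presence" else "absence"
  flags <- predictor_flags(trend_features(cohort, config), config$thresholds)
  preds <- unlist(lapply(config$thresholds, function(th) {
    ids <- predictor_ids(th)
    ids[grepl(paste0("_", dir, "_"), ids)]
  }))
  dplyr::bind_rows(lapply(preds, function(pid)
    evaluate_predictor(cohort, pid, target, config, method, alpha, flags = flags)))
}

#' Performance of guideline risk categories
#'
#' For each of the high and intermediate categories taken as the index test
#' (category membership = test positive), reports the stone yield `x/N`
#' within the category and the metric panel against confirmed stones.
#'
#' @param cohort An eligible `cdl_cohort`.
#' @param guideline `"ASGE2010"`, `"ASGE2019"`, or `"ESGE2019"`.
#' @param ranges A [reference_ranges()].
#' @param method,alpha CI method and level; the normal-approximation
#'   interval is the default for these large-n category rows.
#' @return Tibble: one row per category with `cdl_in_category`,
#'   `n_category`, and the metric panel columns.
#' @export
guideline_performance <- function(cohort, guideline, ranges = reference_ranges(),
                                  method = "wald", alpha = 0.05) {
  assign <- classify_guidelines(cohort, ranges, guideline)
  outcomes <- stats::setNames(cohort$patients$cdl_found, cohort$patients$id)
  rows <- lapply(c("high", "intermediate"), function(cat) {
    f <- stats::setNames(assign$category == cat, assign$id)
    tbl <- build_confusion(f, outcomes, "presence")
    dplyr::bind_cols(
      tibble::tibble(guideline = guideline, category = cat,
                     cdl_in_category = tbl$tp, n_category = tbl$tp + tbl$fp),
      .panel_row(tbl, method, alpha))
  })
  dplyr::bind_rows(rows)
}

#' Format a performance table for display
#'
#' Rounds percentages to one decimal (half away from zero) and renders
#' `point (lo-hi)` strings, with `N/R` for not-reportable estimates.
#'
#' @param tbl Output of [trend_performance_table()] or
#'   [guideline_performance()].
#' @return Tibble of character columns.
#' @export
format_performance <- function(tbl) {
  fmt <- function(point, lo, hi) {
    ifelse(is.na(point), "N/R",
           sprintf("%.1f (%.1f-%.1f)", round_half_up(point),
                   round_half_up(lo), round_half_up(hi)))
  }
  metrics <- c("accuracy", "sensitivity", "specificity", "ppv", "npv")
  out <- tbl[intersect(c("predictor", "target", "guideline", "category",
                         "cdl_in_category", "n_category"), names(tbl))]
  for (m in metrics) {
    out[[m]] <- fmt(tbl[[m]], tbl[[paste0(m, "_lo")]], tbl[[paste0(m, "_hi")]])
  }
  out$n_model <- tbl$n_model
  out
}
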