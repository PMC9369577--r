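test_that("confusion counts follow the target orientation", {
  flags <- c(TRUE, TRUE, FALSE, FALSE)
  outcomes <- c(TRUE, FALSE, TRUE, FALSE)
  tbl <- build_confusion(flags, outcomes, "presence")
  expect_equal(tbl[c("tp", "fp", "fn", "tn")], list(tp = 1, fp = 1, fn = 1, tn = 1))
  expect_equal(tbl$n_model, 4)
  # absence: a flagged stone-free patient is now the true positive
  tbl2 <- build_confusion(flags, outcomes, "absence")
  expect_equal(tbl2[c("tp", "fp", "fn", "tn")], list(tp = 1, fp = 1, fn = 1, tn = 1))

  # unknown flags drop out listwise
  tbl3 <- build_confusion(c(TRUE, NA, FALSE, NA), outcomes, "presence")
  expect_equal(tbl3$n_model, 2)
  expect_equal(tbl3$tp, 1)

  expect_error(build_confusion(c(a = TRUE), c(b = TRUE)), "different patient ids")
})

test_that("random confusion tables equal a brute-force tally and swap roles under orientation", {
  set.seed(51)
  for (rep in 1:50) {
    n <- sample(5:60, 1)
    flags <- sample(c(TRUE, FALSE, NA), n, replace = TRUE)
    outcomes <- sample(c(TRUE, FALSE), n, replace = TRUE)
    p <- build_confusion(flags, outcomes, "presence")
    a <- build_confusion(flags, outcomes, "absence")
    keep <- !is.na(flags)
    expect_equal(p$tp, sum(flags[keep] & outcomes[keep]))
    expect_equal(p$fp, sum(flags[keep] & !outcomes[keep]))
    expect_equal(p$fn, sum(!flags[keep] & outcomes[keep]))
    expect_equal(p$tn, sum(!flags[keep] & !outcomes[keep]))
    # orientation swap: tp<->fp, fn<->tn; total preserved
    expect_equal(a$tp, p$fp)
    expect_equal(a$fp, p$tp)
    expect_equal(a$fn, p$tn)
    expect_equal(a$tn, p$fn)
    expect_equal(a$n_model, p$n_model)
    # duality: the complementary test aimed at the complementary condition
    # trades sensitivity/specificity and PPV/NPV exactly
    dual <- build_confusion(!flags, outcomes, "absence")
    mp <- metric_panel(p); ma <- metric_panel(dual)
    g <- function(panel, m) panel$point[panel$metric == m]
    expect_equal(g(ma, "sensitivity"), g(mp, "specificity"))
    expect_equal(g(ma, "specificity"), g(mp, "sensitivity"))
    expect_equal(g(ma, "ppv"), g(mp, "npv"))
    expect_equal(g(ma, "npv"), g(mp, "ppv"))
    expect_equal(g(ma, "accuracy"), g(mp, "accuracy"))
    # accuracy bounded by the extreme class-conditional rates
    acc <- g(mp, "accuracy")
    if (!is.na(g(mp, "sensitivity")) && !is.na(g(mp, "specificity"))) {
      expect_gte(acc, min(g(mp, "sensitivity"), g(mp, "specificity")) - 1e-9)
      expect_lte(acc, max(g(mp, "sensitivity"), g(mp, "specificity")) + 1e-9)
    }
  }
})

test_that("metric points reproduce published category arithmetic", {
  # 421 stones among 569 high-risk patients: PPV 74.0%
  ppv <- metric(list(tp = 421, fp = 148, fn = 201, tn = 109), "ppv")
  expect_equal(round_half_up(ppv$point), 74.0)
  # 288 flagged of 622 condition-positives: sensitivity 46.3%
  sens <- metric(list(tp = 288, fp = 50, fn = 334, tn = 207), "sensitivity")
  expect_equal(round_half_up(sens$point), 46.3)
  # zero positive calls: PPV not reportable
  nr <- metric(list(tp = 0, fp = 0, fn = 10, tn = 40), "ppv")
  expect_true(is.na(nr$point) && is.na(nr$ci_lower))
})

test_that("exact intervals hit their boundary cases and match the reference implementation", {
  expect_equal(binom_ci(0, 50, "clopper_pearson")[1], 0)
  expect_equal(binom_ci(50, 50, "clopper_pearson")[2], 1)
  expect_error(binom_ci(5, 3), "0 <= x <= n")
  expect_true(all(is.na(binom_ci(0, 0))))

  set.seed(61)
  for (rep in 1:40) {
    n <- sample(1:200, 1)
    x <- sample(0:n, 1)
    got <- binom_ci(x, n, "clopper_pearson")
    want <- stats::binom.test(x, n)$conf.int   # independent oracle
    expect_equal(got, as.numeric(want), tolerance = 1e-10)
  }
})

test_that("Wald and Wilson intervals match independently coded formulas", {
  wald_oracle <- function(x, n, alpha = 0.05) {
    p <- x / n
    z <- stats::qnorm(1 - alpha / 2)
    pmin(1, pmax(0, p + c(-1, 1) * z * sqrt(p * (1 - p) / n)))
  }
  wilson_oracle <- function(x, n, alpha = 0.05) {
    z <- stats::qnorm(1 - alpha / 2)
    p <- x / n
    (p + z^2 / (2 * n) + c(-1, 1) * z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
      (1 + z^2 / n)
  }
  expect_equal(binom_ci(288, 338, "wald"), wald_oracle(288, 338), tolerance = 1e-10)
  # the published large-category interval: 288/338 -> 85.2% (81.4-89.0)
  expect_equal(round_half_up(100 * binom_ci(288, 338, "wald")), c(81.4, 89.0))
  set.seed(62)
  for (rep in 1:25) {
    n <- sample(5:500, 1); x <- sample(0:n, 1)
    expect_equal(binom_ci(x, n, "wald"), wald_oracle(x, n), tolerance = 1e-10)
    expect_equal(binom_ci(x, n, "wilson"), wilson_oracle(x, n), tolerance = 1e-10)
  }
})

test_that("reporting rounds half away from zero at one decimal", {
  expect_equal(round_half_up(73.95), 74.0)
  expect_equal(round_half_up(0.05), 0.1)
  expect_equal(round_half_up(-0.05), -0.1)
  expect_equal(round_half_up(46.25), 46.3)
})

test_that("predictor evaluation composes confusion and metric computation", {
  gen <- generate_cohort(generator_params(n_patients = 200), seed = 71)
  eligible <- apply_eligibility(gen$cohort)$eligible
  cfg <- trend_config()
  flags <- predictor_flags(trend_features(eligible, cfg), cfg$thresholds)
  for (pid in c("TBILI_inc_30", "ALP_dec_50", "TBILI_and_ALT_dec_50")) {
    target <- if (grepl("_inc_", pid)) "presence" else "absence"
    row <- evaluate_predictor(eligible, pid, target, cfg)
    tbl <- build_confusion(stats::setNames(flags[[pid]], flags$id),
                           stats::setNames(eligible$patients$cdl_found,
                                           eligible$patients$id), target)
    for (m in c("accuracy", "sensitivity", "specificity", "ppv", "npv")) {
      want <- metric(tbl, m)
      expect_equal(row[[m]], want$point)
      expect_equal(row[[paste0(m, "_lo")]], want$ci_lower)
      expect_equal(row[[paste0(m, "_hi")]], want$ci_upper)
    }
    expect_equal(row$n_model, tbl$n_model)
  }
})

test_that("a cohort with no decreasing stone-positive patients is perfectly specific for absence", {
  # stones rise, stone-free fall: the decrease flag never fires in positives
  ids <- sprintf("P%02d", 1:20)
  cdl <- rep(c(TRUE, FALSE), each = 10)
  patients <- dplyr::bind_rows(lapply(seq_along(ids), function(i)
    make_patient(ids[i], cdl_found = cdl[i])))
  labs <- dplyr::bind_rows(
    make_labs(ids[cdl], "ALP", -48, 100), make_labs(ids[cdl], "ALP", 0, 160),
    make_labs(ids[!cdl], "ALP", -48, 100), make_labs(ids[!cdl], "ALP", 0, 40))
  cohort <- new_cohort(patients, labs)
  row <- evaluate_predictor(cohort, "ALP_dec_50", "absence")
  expect_equal(row$specificity, 100)
  expect_equal(row$sensitivity, 100)

  # all-flags-false: zero sensitivity, perfect specificity, whatever the target
  flat <- new_cohort(patients, dplyr::bind_rows(
    make_labs(ids, "ALP", -48, 100), make_labs(ids, "ALP", 0, 100)))
  for (target in c("presence", "absence")) {
    row <- evaluate_predictor(flat, "ALP_dec_50", target)
    expect_equal(row$sensitivity, 0)
    expect_equal(row$specificity, 100)
  }
})

test_that("guideline performance reproduces the published ASGE 2010 row", {
  cohort <- published_category_cohort()
  perf <- guideline_performance(cohort, "ASGE2010", method = "wald")
  high <- perf[perf$category == "high", ]
  expect_equal(high$cdl_in_category, 421)
  expect_equal(high$n_category, 569)
  expect_equal(round_half_up(high$ppv), 74.0)
  expect_equal(round_half_up(high$sensitivity), 67.7)
  expect_equal(round_half_up(c(high$sensitivity_lo, high$sensitivity_hi)),
               c(64.0, 71.4))
  int <- perf[perf$category == "intermediate", ]
  expect_equal(int$cdl_in_category, 172)
  expect_equal(int$n_category, 258)

  # degenerate single-category cohort: no intermediate calls, PPV not reportable
  solo <- new_cohort(make_patient("P1", stone_on_us = TRUE), empty_labs())
  perf <- guideline_performance(solo, "ASGE2010")
  int <- perf[perf$category == "intermediate", ]
  expect_equal(int$n_category, 0)
  expect_true(is.na(int$ppv))
})

test_that("random category assignments match a brute-force tally", {
  set.seed(81)
  n <- 120
  ids <- sprintf("P%03d", seq_len(n))
  cats <- sample(c("high", "intermediate", "low"), n, replace = TRUE)
  cdl <- sample(c(TRUE, FALSE), n, replace = TRUE)
  patients <- dplyr::bind_rows(lapply(seq_len(n), function(i)
    make_patient(ids[i], cdl_found = cdl[i],
                 stone_on_us = cats[i] == "high",
                 age = if (cats[i] == "intermediate") 70 else 40)))
  cohort <- new_cohort(patients, empty_labs())
  perf <- guideline_performance(cohort, "ASGE2010")
  for (cat in c("high", "intermediate")) {
    row <- perf[perf$category == cat, ]
    expect_equal(row$cdl_in_category, sum(cdl & cats == cat))
    expect_equal(row$n_category, sum(cats == cat))
    expect_equal(row$sensitivity, 100 * sum(cdl & cats == cat) / sum(cdl))
  }
})

test_that("formatted tables render N/R and one-decimal interval strings", {
  solo <- new_cohort(make_patient("P1", stone_on_us = TRUE), empty_labs())
  fmt <- format_performance(guideline_performance(solo, "ASGE2010"))
  expect_equal(fmt$ppv[fmt$category == "intermediate"], "N/R")
  expect_match(fmt$ppv[fmt$category == "high"], "^100\\.0 \\(")
})
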