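#' Trend-analysis configuration
#'
#' @param window_hours Look-back window before the procedure, in hours
#'   (default 72; day-of-procedure draws are included at `t_hours <= 0`).
#' @param thresholds Relative-change thresholds defining a "significant"
#'   trend (default 30% and 50%).
#' @param analytes Analytes whose trends act as index tests.
#' @param anchor_mode `"pairwise"` (default) scans every time-ordered pair of
#'   measurements, so any rise or fall inside the window — including within
#'   48, 24, or 12 h — is captured; `"last_value"` anchors the change to the
#'   measurement closest to the procedure.
#' @return A `trend_config` list.
#' @export
trend_config <- function(window_hours = 72, thresholds = c(0.30, 0.50),
                         analytes = c("TBILI", "ALT", "ALP"),
                         anchor_mode = c("pairwise", "last_value")) {
  .assert(window_hours > 0, "window_hours must be positive")
  .assert(all(thresholds > 0), "thresholds must be positive fractions")
  .assert(all(analytes %in% ANALYTES), "unknown analyte in trend config")
  structure(list(window_hours = window_hours, thresholds = sort(thresholds),
                 analytes = analytes, anchor_mode = match.arg(anchor_mode)),
            class = "trend_config")
}

#' Extract one analyte's in-window series for a patient
#'
#' Keeps measurements with `-window_hours <= t_hours <= 0`, ascending in
#' time, with bilirubin converted to the canonical unit (umol/L) so values
#' reported in mg/dL compare correctly.
#'
#' @param labs Lab rows for a single patient.
#' @param analyte Analyte code.
#' @param window_hours Window size in hours.
#' @return Tibble with `t_hours` and `value` (canonical units).
#' @export
extract_window <- function(labs, analyte, window_hours = 72) {
  .assert(analyte %in% ANALYTES, "unknown analyte '%s'", analyte)
  rows <- labs[labs$analyte == analyte &
                 labs$t_hours >= -window_hours & labs$t_hours <= 0, , drop = FALSE]
  value <- rows$value
  if (analyte %in% c("TBILI", "DBILI") && nrow(rows) > 0) {
    value <- ifelse(rows$unit == "mg/dL", value * BILI_UMOL_PER_MG_DL, value)
  }
  ord <- order(rows$t_hours)
  tibble::tibble(t_hours = rows$t_hours[ord], value = value[ord])
}

#' Extremes of relative change over a time-ordered series
#'
#' Scans ordered pairs (earlier value as denominator): the maximal relative
#' increase is `max(0, max_ij (v_j - v_i) / v_i)` over all `i < j`, and the
#' maximal relative decrease is `max(0, max_ij (v_i - v_j) / v_i)`. The two
#' are computed independently, so a non-monotone series can exceed a
#' threshold in both directions. Pairs whose earlier value is zero are
#' skipped; if no usable pair remains (or fewer than two measurements exist)
#' both extremes are `NA`. Ties among extreme-achieving pairs resolve to the
#' earliest pair in time order.
#'
#' @param series Tibble from [extract_window()] (or any tibble with
#'   `t_hours`, `value` in ascending time order), or a plain numeric vector.
#' @param anchor_mode See [trend_config()].
#' @return List: `max_rel_increase`, `max_rel_decrease`, `n_measurements`,
#'   `inc_pair`, `dec_pair` (each `c(t_i, v_i, t_j, v_j)` or `NULL`).
#' @export
percent_change_extremes <- function(series, anchor_mode = "pairwise") {
  if (is.numeric(series)) series <- tibble::tibble(t_hours = seq_along(series), value = series)
  v <- series$value
  t <- series$t_hours
  n <- length(v)
  out <- list(max_rel_increase = NA_real_, max_rel_decrease = NA_real_,
              n_measurements = n, inc_pair = NULL, dec_pair = NULL)
  if (n < 2) return(out)
  best_inc <- -Inf
  best_dec <- -Inf
  usable <- FALSE
  j_set <- if (anchor_mode == "last_value") n else 2:n
  for (j in j_set) {
    for (i in seq_len(j - 1)) {
      if (v[i] == 0) next
      usable <- TRUE
      inc <- (v[j] - v[i]) / v[i]
      dec <- (v[i] - v[j]) / v[i]
      if (inc > best_inc) {
        best_inc <- inc
        out$inc_pair <- c(t[i], v[i], t[j], v[j])
      }
      if (dec > best_dec) {
        best_dec <- dec
        out$dec_pair <- c(t[i], v[i], t[j], v[j])
      }
    }
  }
  if (!usable) return(out)
  out$max_rel_increase <- max(0, best_inc)
  out$max_rel_decrease <- max(0, best_dec)
  out
}

#' Per-patient trend features for a cohort
#'
#' @param cohort A `cdl_cohort`.
#' @param config A [trend_config()].
#' @return Tibble with one row per patient x analyte: `id`, `analyte`,
#'   `n_measurements`, `max_rel_increase`, `max_rel_decrease` (`NA` when the
#'   trend is undefined for that patient).
#' @export
trend_features <- function(cohort, config = trend_config()) {
  ids <- cohort$patients$id
  labs_split <- split(cohort$labs, factor(cohort$labs$id, levels = ids))
  rows <- lapply(config$analytes, function(a) {
    feats <- lapply(ids, function(pid) {
      s <- extract_window(labs_split[[pid]], a, config$window_hours)
      e <- percent_change_extremes(s, config$anchor_mode)
      c(e$n_measurements, e$max_rel_increase, e$max_rel_decrease)
    })
    m <- do.call(rbind, feats)
    tibble::tibble(id = ids, analyte = a, n_measurements = as.integer(m[, 1]),
                   max_rel_increase = m[, 2], max_rel_decrease = m[, 3])
  })
  dplyr::bind_rows(rows)
}

#' Predictor identifiers for one threshold
#'
#' Twelve index tests per threshold: single-analyte increase/decrease for
#' total bilirubin, ALP, and ALT; bilirubin-OR-ALT; bilirubin-AND-ALT; and
#' any-of-the-three.
#'
#' @param threshold Fraction, e.g. `0.3`.
#' @return Character vector of predictor ids, e.g. `"TBILI_inc_30"`.
#' @export
predictor_ids <- function(threshold) {
  fam <- c("TBILI", "ALP", "ALT", "TBILI_or_ALT", "TBILI_and_ALT", "any")
  pct <- round(100 * threshold)
  as.vector(t(outer(fam, c("inc", "dec"), function(f, d) paste0(f, "_", d, "_", pct))))
}

#' Threshold flags for every predictor
#'
#' A single-analyte flag is `TRUE` when the analyte's maximal relative change
#' in the window reaches the threshold, and `NA` when the trend is undefined
#' (fewer than two usable in-window values). Combined predictors use
#' three-valued logic: AND is unknown whenever either operand is unknown; OR
#' is `TRUE` as soon as one defined operand is `TRUE`, and unknown only when
#' no defined operand is `TRUE` and some operand is unknown. Patients with
#' unknown flags drop out of that predictor's model, which is why the
#' modelled-n differs across predictors.
#'
#' @param features Tibble from [trend_features()].
#' @param thresholds Fractions (default `c(0.3, 0.5)`).
#' @return Wide tibble: `id` plus one logical column per predictor id.
#' @export
predictor_flags <- function(features, thresholds = c(0.3, 0.5)) {
  get <- function(analyte, what) {
    f <- features[features$analyte == analyte, ]
    stats::setNames(f[[what]], f$id)[unique(features$id)]
  }
  ids <- unique(features$id)
  out <- tibble::tibble(id = ids)
  for (th in thresholds) {
    pct <- round(100 * th)
    for (dir in c("inc", "dec")) {
      what <- if (dir == "inc") "max_rel_increase" else "max_rel_decrease"
      single <- lapply(c(TBILI = "TBILI", ALP = "ALP", ALT = "ALT"),
                       function(a) get(a, what) >= th)
      out[[paste0("TBILI_", dir, "_", pct)]] <- unname(single$TBILI)
      out[[paste0("ALP_", dir, "_", pct)]] <- unname(single$ALP)
      out[[paste0("ALT_", dir, "_", pct)]] <- unname(single$ALT)
      out[[paste0("TBILI_or_ALT_", dir, "_", pct)]] <-
        unname(mapply(or3, single$TBILI, single$ALT))
      out[[paste0("TBILI_and_ALT_", dir, "_", pct)]] <-
        unname(mapply(and3, single$TBILI, single$ALT))
      out[[paste0("any_", dir, "_", pct)]] <-
        unname(mapply(or3, single$TBILI, single$ALP, single$ALT))
    }
  }
  out
}

#' Distribution of per-patient percent change by outcome group
#'
#' The per-patient signed change is whichever of the maximal increase and the
#' (negated) maximal decrease has the larger magnitude (ties resolve to the
#' increase). Kernel densities are estimated per outcome group on a common
#' grid and renormalised so each integrates to 1 by the trapezoid rule.
#'
#' @param cohort An eligible `cdl_cohort` with known `cdl_found`.
#' @param analyte Analyte code.
#' @param config A [trend_config()].
#' @return List: `samples` (tibble `id`, `cdl`, `change`) and `density`
#'   (tibble `x`, `density_positive`, `density_negative`, or `NULL` when a
#'   group has fewer than two defined changes — a warning is raised and the
#'   raw samples are still returned).
#' @export
percent_change_distribution <- function(cohort, analyte, config = trend_config()) {
  feats <- trend_features(cohort, trend_config(config$window_hours,
                                               config$thresholds, analyte,
                                               config$anchor_mode))
  signed <- ifelse(feats$max_rel_increase >= feats$max_rel_decrease,
                   feats$max_rel_increase, -feats$max_rel_decrease)
  samples <- tibble::tibble(
    id = feats$id,
    cdl = cohort$patients$cdl_found[match(feats$id, cohort$patients$id)],
    change = signed)
  samples <- samples[!is.na(samples$change) & !is.na(samples$cdl), , drop = FALSE]
  pos <- samples$change[samples$cdl]
  neg <- samples$change[!samples$cdl]
  if (length(pos) < 2 || length(neg) < 2) {
    warning("an outcome group has fewer than 2 defined percent changes; density omitted")
    return(list(samples = samples, density = NULL))
  }
  lims <- range(c(pos, neg))
  pad <- 0.2 * diff(lims) + 1e-9
  grid_density <- function(x) {
    d <- stats::density(x, from = lims[1] - pad, to = lims[2] + pad, n = 512)
    d$y / .trapz(d$x, d$y)
  }
  x <- stats::density(pos, from = lims[1] - pad, to = lims[2] + pad, n = 512)$x
  list(samples = samples,
       density = tibble::tibble(x = x,
                                density_positive = grid_density(pos),
                                density_negative = grid_density(neg)))
}
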