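#' Bilirubin unit conversion factor
#'
#' 1 mg/dL of bilirubin is 17.1 umol/L.
#' @export
BILI_UMOL_PER_MG_DL <- 17.1

#' Convert bilirubin between mg/dL and umol/L
#'
#' Guideline thresholds are stated in mg/dL while many laboratories report
#' umol/L; classification is invariant to the reporting unit.
#'
#' @param value Numeric vector of concentrations.
#' @param from,to `"mg/dL"` or `"umol/L"`.
#' @return Converted values.
#' @export
convert_bilirubin <- function(value, from, to) {
  units <- c("mg/dL", "umol/L")
  .assert(from %in% units && to %in% units, "unknown bilirubin unit")
  if (from == to) return(value)
  if (from == "mg/dL") value * BILI_UMOL_PER_MG_DL else value / BILI_UMOL_PER_MG_DL
}

#' Laboratory reference ranges and guideline cut-offs
#'
#' Upper limits of normal (ULN) are laboratory-specific; the defaults here
#' are typical adult reference ranges (total bilirubin 21 umol/L, ALT and
#' AST 40 U/L, ALP 130 U/L, GGT 60 U/L) and can be overridden per site,
#' directly or from a YAML file with keys `uln`, `bili_band_mg_dl`,
#' `cbd_cutoff_mm`, `age_cutoff_years`. A value is "abnormal" when strictly
#' above its ULN. The bilirubin band 1.8-4 mg/dL is closed on both ends;
#' "bilirubin > 4 mg/dL" is strict.
#'
#' @param uln Named vector of upper limits in canonical units.
#' @param bili_band_mg_dl Lower/upper bounds of the intermediate bilirubin
#'   band, mg/dL.
#' @param cbd_cutoff_mm Common-bile-duct dilation cut-off, millimetres.
#' @param age_cutoff_years Age cut-off for the intermediate criterion.
#' @param yaml_path Optional YAML file overriding any of the above.
#' @return A `reference_ranges` list.
#' @export
reference_ranges <- function(uln = c(TBILI = 21, ALT = 40, AST = 40, ALP = 130, GGT = 60),
                             bili_band_mg_dl = c(1.8, 4),
                             cbd_cutoff_mm = 6,
                             age_cutoff_years = 55,
                             yaml_path = NULL) {
  r <- list(uln = uln, bili_band_mg_dl = bili_band_mg_dl,
            cbd_cutoff_mm = cbd_cutoff_mm, age_cutoff_years = age_cutoff_years)
  if (!is.null(yaml_path)) {
    y <- yaml::read_yaml(yaml_path)
    if (!is.null(y$uln)) r$uln[names(y$uln)] <- unlist(y$uln)
    for (k in c("bili_band_mg_dl", "cbd_cutoff_mm", "age_cutoff_years")) {
      if (!is.null(y[[k]])) r[[k]] <- unlist(y[[k]])
    }
  }
  .assert(all(r$uln > 0) && all(r$bili_band_mg_dl > 0) && r$cbd_cutoff_mm > 0,
          "reference limits must be positive")
  structure(r, class = "reference_ranges")
}

# Most recent pre-procedure value per patient x analyte, canonical units.
closest_labs <- function(cohort) {
  labs <- cohort$labs[cohort$labs$t_hours <= 0, , drop = FALSE]
  if (nrow(labs) == 0) return(tibble::tibble(id = character(0)))
  bili <- labs$analyte %in% c("TBILI", "DBILI") & labs$unit == "mg/dL"
  labs$value[bili] <- labs$value[bili] * BILI_UMOL_PER_MG_DL
  labs |>
    dplyr::group_by(.data$id, .data$analyte) |>
    dplyr::slice_max(.data$t_hours, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("id", "analyte", "value") |>
    tidyr::pivot_wider(names_from = "analyte", values_from = "value")
}

#' Abnormal liver biochemistry flags
#'
#' Uses each patient's measurement closest in time before the procedure.
#' An analyte is abnormal when strictly above its ULN; unmeasured analytes
#' are unknown. The aggregates OR over the defined analytes and are unknown
#' only when no relevant analyte was measured.
#'
#' @param cohort A `cdl_cohort`.
#' @param ranges A [reference_ranges()].
#' @return Tibble: `id`, one logical column per ULN analyte,
#'   `other_than_bilirubin`, and `any_lft`.
#' @export
abnormal_lfts <- function(cohort, ranges = reference_ranges()) {
  wide <- closest_labs(cohort)
  ids <- cohort$patients$id
  out <- tibble::tibble(id = ids)
  for (a in names(ranges$uln)) {
    v <- if (a %in% names(wide)) wide[[a]][match(ids, wide$id)] else rep(NA_real_, length(ids))
    out[[a]] <- v > ranges$uln[[a]]
  }
  non_bili <- setdiff(names(ranges$uln), c("TBILI", "DBILI"))
  # OR over the measured analytes; unknown only when none was measured
  row_or_defined <- function(cols) {
    if (nrow(out) == 0) return(logical(0))
    apply(as.matrix(out[cols]), 1, function(r) {
      if (all(is.na(r))) NA else any(r, na.rm = TRUE)
    })
  }
  out$other_than_bilirubin <- row_or_defined(non_bili)
  out$any_lft <- row_or_defined(names(ranges$uln))
  out
}

# Elementary criteria shared by the three guidelines, vectorised over the
# cohort. Missing imaging or flags count as criterion-not-met (bedside use:
# a finding you do not have cannot trigger a criterion), so every patient
# receives a category.
.guideline_inputs <- function(cohort, ranges) {
  p <- cohort$patients
  wide <- closest_labs(cohort)
  tb_umol <- if ("TBILI" %in% names(wide)) wide$TBILI[match(p$id, wide$id)] else rep(NA_real_, nrow(p))
  tb_mg <- tb_umol / BILI_UMOL_PER_MG_DL
  ab <- abnormal_lfts(cohort, ranges)
  band <- ranges$bili_band_mg_dl
  list(
    id = p$id,
    stone_us = p$stone_on_us %in% TRUE,
    stone_any_imaging = (p$stone_on_us %in% TRUE) | (p$stone_on_ct_mri %in% TRUE),
    cholangitis = p$cholangitis %in% TRUE,
    bili_gt_upper = !is.na(tb_mg) & tb_mg > band[2],
    bili_in_band = !is.na(tb_mg) & tb_mg >= band[1] & tb_mg <= band[2],
    bili_ge_lower = !is.na(tb_mg) & tb_mg >= band[1],
    cbd_dilated = !is.na(p$cbd_mm) & p$cbd_mm > ranges$cbd_cutoff_mm,
    abnormal_non_bili = ab$other_than_bilirubin %in% TRUE,
    abnormal_any = ab$any_lft %in% TRUE,
    pancreatitis = p$gallstone_pancreatitis %in% TRUE,
    age_gt_cutoff = !is.na(p$age) & p$age > ranges$age_cutoff_years
  )
}

.assemble_assignment <- function(id, guideline, high, intermediate) {
  n <- length(id)
  cat_of <- function(i) {
    h <- names(high)[vapply(high, `[`, logical(1), i)]
    m <- names(intermediate)[vapply(intermediate, `[`, logical(1), i)]
    if (length(h) > 0) list("high", c(h, m))
    else if (length(m) > 0) list("intermediate", m)
    else list("low", character(0))
  }
  res <- lapply(seq_len(n), cat_of)
  tibble::tibble(
    id = id, guideline = guideline,
    category = vapply(res, function(r) r[[1]], character(1)),
    triggered = vapply(res, function(r) paste(r[[2]], collapse = ";"), character(1)))
}

#' Pre-test probability of duct stones under the ASGE 2010 criteria
#'
#' High: stone on ultrasound, ascending cholangitis, bilirubin > 4 mg/dL, or
#' bilirubin 1.8-4 mg/dL together with a CBD > 6 mm. Intermediate: bilirubin
#' in the 1.8-4 band, dilated CBD, abnormal non-bilirubin liver tests,
#' gallstone pancreatitis, or age > 55. Low: none of the above.
#'
#' @param cohort A `cdl_cohort`.
#' @param ranges A [reference_ranges()].
#' @return Tibble: `id`, `guideline`, `category`
#'   (`high`/`intermediate`/`low`), `triggered` (criterion ids, `;`-joined).
#' @export
classify_asge2010 <- function(cohort, ranges = reference_ranges()) {
  g <- .guideline_inputs(cohort, ranges)
  high <- list(stone_on_us = g$stone_us,
               cholangitis = g$cholangitis,
               bili_gt_4 = g$bili_gt_upper,
               bili_band_and_cbd = g$bili_in_band & g$cbd_dilated)
  intermediate <- list(bili_band = g$bili_in_band,
                       cbd_gt_6 = g$cbd_dilated,
                       abnormal_non_bili_lfts = g$abnormal_non_bili,
                       gallstone_pancreatitis = g$pancreatitis,
                       age_gt_55 = g$age_gt_cutoff)
  .assemble_assignment(g$id, "ASGE2010", high, intermediate)
}

#' Pre-test probability under the ASGE 2019 criteria
#'
#' The 2019 revision tightens the high category: stone on ultrasound *or*
#' cross-sectional imaging, cholangitis, or bilirubin > 4 mg/dL *combined
#' with* a dilated CBD; bilirubin >= 1.8 mg/dL alone is now intermediate.
#'
#' @inheritParams classify_asge2010
#' @inherit classify_asge2010 return
#' @export
classify_asge2019 <- function(cohort, ranges = reference_ranges()) {
  g <- .guideline_inputs(cohort, ranges)
  high <- list(stone_on_imaging = g$stone_any_imaging,
               cholangitis = g$cholangitis,
               bili_gt_4_and_cbd = g$bili_gt_upper & g$cbd_dilated)
  intermediate <- list(bili_ge_1.8 = g$bili_ge_lower,
                       cbd_gt_6 = g$cbd_dilated,
                       abnormal_non_bili_lfts = g$abnormal_non_bili,
                       gallstone_pancreatitis = g$pancreatitis,
                       age_gt_55 = g$age_gt_cutoff)
  .assemble_assignment(g$id, "ASGE2019", high, intermediate)
}

#' Pre-test probability under the ESGE 2019 criteria
#'
#' High: cholangitis or stone on ultrasound. Intermediate: any abnormal
#' liver biochemistry or CBD > 6 mm. Low: neither.
#'
#' @inheritParams classify_asge2010
#' @inherit classify_asge2010 return
#' @export
classify_esge2019 <- function(cohort, ranges = reference_ranges()) {
  g <- .guideline_inputs(cohort, ranges)
  high <- list(cholangitis = g$cholangitis,
               stone_on_us = g$stone_us)
  intermediate <- list(any_abnormal_lfts = g$abnormal_any,
                       cbd_gt_6 = g$cbd_dilated)
  .assemble_assignment(g$id, "ESGE2019", high, intermediate)
}

#' Risk categories under all three guidelines
#'
#' @inheritParams classify_asge2010
#' @param guidelines Subset of `c("ASGE2010", "ASGE2019", "ESGE2019")`.
#' @return Row-bound assignment tibble across guidelines.
#' @export
classify_guidelines <- function(cohort, ranges = reference_ranges(),
                                guidelines = c("ASGE2010", "ASGE2019", "ESGE2019")) {
  fns <- list(ASGE2010 = classify_asge2010, ASGE2019 = classify_asge2019,
              ESGE2019 = classify_esge2019)
  unknown <- setdiff(guidelines, names(fns))
  .assert(length(unknown) == 0, "unknown guideline(s): %s", paste(unknown, collapse = ", "))
  dplyr::bind_rows(lapply(guidelines, function(gl) fns[[gl]](cohort, ranges)))
}
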