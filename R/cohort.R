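#' Cohort container
#'
#' A cohort is a pair of tables: one row per patient (demographics, clinical
#' flags, imaging findings, procedure outcome) and a long lab table (one row
#' per measurement, time offsets in hours relative to procedure start, with
#' pre-procedure draws at `t_hours <= 0`).
#'
#' @param patients Tibble with the columns of [patient_columns()].
#' @param labs Tibble with columns `id`, `analyte`, `t_hours`, `value`, `unit`.
#' @return An object of class `cdl_cohort`.
#' @export
new_cohort <- function(patients, labs) {
  patients <- tibble::as_tibble(patients)
  labs <- tibble::as_tibble(labs)
  missing_p <- setdiff(patient_columns(), names(patients))
  .assert(length(missing_p) == 0,
          "patient table is missing columns: %s", paste(missing_p, collapse = ", "))
  missing_l <- setdiff(lab_columns(), names(labs))
  .assert(length(missing_l) == 0,
          "lab table is missing columns: %s", paste(missing_l, collapse = ", "))
  .assert(!anyDuplicated(patients$id), "duplicate patient ids in cohort")
  validate_labs(labs)
  orphans <- setdiff(labs$id, patients$id)
  .assert(length(orphans) == 0,
          "lab rows reference unknown patient ids: %s",
          paste(sort(unique(orphans)), collapse = ", "))
  labs <- dplyr::arrange(labs, .data$id, .data$t_hours)
  structure(list(patients = patients, labs = labs), class = "cdl_cohort")
}

#' @export
print.cdl_cohort <- function(x, ...) {
  cat(sprintf("<cdl_cohort> %d patients, %d lab measurements\n",
              nrow(x$patients), nrow(x$labs)))
  if (nrow(x$patients) > 0 && !all(is.na(x$patients$cdl_found))) {
    pos <- sum(x$patients$cdl_found, na.rm = TRUE)
    cat(sprintf("  choledocholithiasis confirmed: %d (%.1f%%)\n",
                pos, 100 * pos / sum(!is.na(x$patients$cdl_found))))
  }
  invisible(x)
}

#' Canonical column sets for the cohort tables
#'
#' @return Character vector of column names.
#' @export
patient_columns <- function() {
  c("id", "age", "sex", "inpatient", "cholangitis", "gallstone_pancreatitis",
    "prior_cholecystectomy", "prior_sphincterotomy", "biliary_stent",
    "indication_suspected_cdl", "stone_on_us", "stone_on_ct_mri", "cbd_mm",
    "imaging_days_before", "proc_type", "successful", "cdl_found",
    "days_since_prior_procedure")
}

#' @rdname patient_columns
#' @export
lab_columns <- function() c("id", "analyte", "t_hours", "value", "unit")

validate_labs <- function(labs) {
  bad <- setdiff(unique(labs$analyte), ANALYTES)
  .assert(length(bad) == 0, "unknown analyte code(s): %s", paste(bad, collapse = ", "))
  .assert(all(labs$value >= 0, na.rm = TRUE), "negative laboratory values present")
  legal <- mapply(function(a, u) u %in% .analyte_units[[a]], labs$analyte, labs$unit)
  .assert(all(legal),
          "illegal unit for analyte in rows: %s",
          paste(utils::head(which(!legal), 10), collapse = ", "))
  invisible(labs)
}

#' File schema for cohort tables
#'
#' Describes how the two delimited files are laid out: delimiter,
#' missing-value token, and (optionally) a renaming from canonical column
#' names to the names used in the files.
#'
#' @param delim Field delimiter (default tab).
#' @param na Missing-value token (default empty string).
#' @param patient_cols,lab_cols Named character vectors mapping canonical
#'   column names to file column names; `NULL` means identity.
#' @return A `cdl_schema` list.
#' @export
cohort_schema <- function(delim = "\t", na = "", patient_cols = NULL, lab_cols = NULL) {
  structure(list(delim = delim, na = na,
                 patient_cols = patient_cols, lab_cols = lab_cols),
            class = "cdl_schema")
}

.apply_col_map <- function(df, map, canonical, what) {
  if (!is.null(map)) {
    .assert(all(names(map) %in% canonical), "unknown canonical column in %s map", what)
    for (canon in names(map)) {
      .assert(map[[canon]] %in% names(df),
              "%s file lacks expected column '%s'", what, map[[canon]])
      names(df)[names(df) == map[[canon]]] <- canon
    }
  }
  missing <- setdiff(canonical, names(df))
  .assert(length(missing) == 0,
          "%s file is missing columns: %s", what, paste(missing, collapse = ", "))
  df[canonical]
}

#' Read a cohort from delimited files
#'
#' Reads the patient-level and long-format lab tables, joins labs to patients
#' by id, validates analyte codes / units / numeric values, and returns a
#' [new_cohort()] with labs in time order. Malformed lab values and orphan
#' lab rows are hard errors naming the offending data rows / ids.
#'
#' @param patient_path,lab_path Paths to the two delimited files.
#' @param schema A [cohort_schema()].
#' @return A `cdl_cohort`.
#' @export
read_cohort <- function(patient_path, lab_path, schema = cohort_schema()) {
  .assert(file.exists(patient_path), "patient table not found: %s", patient_path)
  .assert(file.exists(lab_path), "lab table not found: %s", lab_path)

  # read as character and coerce below: type guessing would turn sex "F"
  # into a logical and all-missing integer columns into logicals
  patients <- readr::read_delim(
    patient_path, delim = schema$delim, na = schema$na,
    col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE, progress = FALSE)
  patients <- .apply_col_map(patients, schema$patient_cols, patient_columns(), "patient")
  types <- list(id = as.character, age = as.numeric, sex = as.character,
                inpatient = as.logical, cholangitis = as.logical,
                gallstone_pancreatitis = as.logical,
                prior_cholecystectomy = as.logical,
                prior_sphincterotomy = as.logical, biliary_stent = as.logical,
                indication_suspected_cdl = as.logical,
                stone_on_us = as.logical, stone_on_ct_mri = as.logical,
                cbd_mm = as.numeric, imaging_days_before = as.integer,
                proc_type = as.character, successful = as.logical,
                cdl_found = as.logical, days_since_prior_procedure = as.integer)
  for (col in names(types)) patients[[col]] <- types[[col]](patients[[col]])

  labs <- readr::read_delim(
    lab_path, delim = schema$delim, na = schema$na,
    col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE, progress = FALSE)
  labs <- .apply_col_map(labs, schema$lab_cols, lab_columns(), "lab")

  num <- function(col, name) {
    parsed <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(parsed))
    .assert(length(bad) == 0,
            "non-numeric %s in lab table data row(s): %s", name,
            paste(utils::head(bad, 10), collapse = ", "))
    parsed
  }
  labs$t_hours <- num(labs$t_hours, "t_hours")
  labs$value <- num(labs$value, "value")
  new_cohort(patients, labs)
}

#' Write a cohort to delimited files
#'
#' Numeric fields are written at full (shortest round-trip) precision and
#' units verbatim, so `read_cohort()` on the output reproduces the cohort
#' exactly.
#'
#' @param cohort A `cdl_cohort`.
#' @param patient_path,lab_path Output paths.
#' @param schema A [cohort_schema()]; only `delim` and `na` are used.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, patient_path, lab_path, schema = cohort_schema()) {
  readr::write_delim(cohort$patients, patient_path, delim = schema$delim, na = schema$na)
  readr::write_delim(cohort$labs, lab_path, delim = schema$delim, na = schema$na)
  invisible(c(patient_path, lab_path))
}
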