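# Builders for tiny in-code fixtures.

# One patient row with sensible eligible defaults; override any field.
make_patient <- function(id, ...) {
  p <- tibble::tibble(
    id = id, age = 45, sex = "F", inpatient = TRUE, cholangitis = FALSE,
    gallstone_pancreatitis = FALSE, prior_cholecystectomy = FALSE,
    prior_sphincterotomy = FALSE, biliary_stent = FALSE,
    indication_suspected_cdl = TRUE, stone_on_us = FALSE,
    stone_on_ct_mri = FALSE, cbd_mm = 4, imaging_days_before = 2L,
    proc_type = "ERCP", successful = TRUE, cdl_found = TRUE,
    days_since_prior_procedure = NA_integer_)
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  p
}

make_labs <- function(id, analyte, t_hours, value, unit = NULL) {
  if (is.null(unit)) {
    unit <- ifelse(analyte %in% c("TBILI", "DBILI"), "umol/L", "U/L")
  }
  tibble::tibble(id = id, analyte = analyte, t_hours = t_hours,
                 value = value, unit = unit)
}

empty_labs <- function() make_labs(character(0), character(0), numeric(0), numeric(0))

# A cohort engineered so ASGE 2010 classification reproduces the published
# category-by-outcome counts: 421/569 high (stone on US), 172/258
# intermediate (age > 55 only), 29/52 low. Labs are empty; all other flags
# neutral.
published_category_cohort <- function() {
  n_high_pos <- 421; n_high_neg <- 148
  n_int_pos <- 172; n_int_neg <- 86
  n_low_pos <- 29; n_low_neg <- 23
  n <- n_high_pos + n_high_neg + n_int_pos + n_int_neg + n_low_pos + n_low_neg
  ids <- sprintf("P%03d", seq_len(n))
  cdl <- rep(c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
             c(n_high_pos, n_high_neg, n_int_pos, n_int_neg, n_low_pos, n_low_neg))
  cat_block <- rep(c("high", "high", "int", "int", "low", "low"),
                   c(n_high_pos, n_high_neg, n_int_pos, n_int_neg, n_low_pos, n_low_neg))
  patients <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    make_patient(ids[i], cdl_found = cdl[i],
                 stone_on_us = cat_block[i] == "high",
                 age = if (cat_block[i] == "int") 60 else 45)
  }))
  new_cohort(patients, empty_labs())
}

# random positive lab series for property tests
random_series <- function(n, zero_prob = 0) {
  v <- stats::rlnorm(n, log(100), 0.8)
  v[stats::runif(n) < zero_prob] <- 0
  tibble::tibble(t_hours = sort(stats::runif(n, -72, 0)), value = v)
}

# Independent brute-force oracle: enumerate every time-ordered pair.
extremes_oracle <- function(values) {
  n <- length(values)
  inc <- dec <- c()
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1)) {
      if (values[i] == 0) next
      inc <- c(inc, (values[j] - values[i]) / values[i])
      dec <- c(dec, (values[i] - values[j]) / values[i])
    }
  }
  if (is.null(inc)) {
    list(max_rel_increase = NA_real_, max_rel_decrease = NA_real_)
  } else {
    list(max_rel_increase = max(0, max(inc)), max_rel_decrease = max(0, max(dec)))
  }
}
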