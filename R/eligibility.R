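#' Eligibility rules, in application order
#'
#' The study flow removes, in order: non-adults, out-patients, procedures not
#' done for suspected duct stones (including cholangitis indications), prior
#' cholecystectomy / sphincterotomy / indwelling biliary stent, unsuccessful
#' procedures, repeat procedures within 14 days, and records without the
#' minimum data needed to analyse them (a known procedure outcome and at
#' least one pre-procedure lab). Each excluded patient is attributed to the
#' first rule that removes them, so the tally partitions the exclusions.
#'
#' @param enable Character vector of rule names to apply, in order. Defaults
#'   to all rules.
#' @return Character vector of rule names (ordered).
#' @export
eligibility_rules <- function(enable = names(.eligibility_predicates)) {
  unknown <- setdiff(enable, names(.eligibility_predicates))
  .assert(length(unknown) == 0,
          "unknown eligibility rule(s): %s", paste(unknown, collapse = ", "))
  enable
}

# Each predicate returns TRUE for patients KEPT by the rule. Missing values
# in required flags fail the rule (they are what "missing data" exclusions
# are), except an unknown prior-procedure interval, which means no prior
# procedure on record.
.eligibility_predicates <- list(
  adult = function(p, labs_by_id) !is.na(p$age) & p$age >= 18,
  inpatient = function(p, labs_by_id) p$inpatient %in% TRUE,
  indication_suspected_cdl = function(p, labs_by_id)
    p$indication_suspected_cdl %in% TRUE & !(p$cholangitis %in% TRUE),
  no_prior_cholecystectomy = function(p, labs_by_id) !(p$prior_cholecystectomy %in% TRUE),
  no_prior_sphincterotomy = function(p, labs_by_id) !(p$prior_sphincterotomy %in% TRUE),
  no_biliary_stent = function(p, labs_by_id) !(p$biliary_stent %in% TRUE),
  procedure_successful = function(p, labs_by_id) p$successful %in% TRUE,
  no_recent_prior_procedure = function(p, labs_by_id)
    is.na(p$days_since_prior_procedure) | p$days_since_prior_procedure > 14,
  data_complete = function(p, labs_by_id)
    !is.na(p$cdl_found) & p$id %in% labs_by_id
)

#' Apply the eligibility filter
#'
#' @param cohort A `cdl_cohort`.
#' @param rules Ordered rule names from [eligibility_rules()].
#' @return A list with `eligible` (a `cdl_cohort`), `tally` (named integer
#'   vector: patients removed by each rule, disjoint by construction),
#'   and `n_input`. `nrow(eligible$patients) + sum(tally) == n_input` always.
#' @export
apply_eligibility <- function(cohort, rules = eligibility_rules()) {
  rules <- eligibility_rules(rules)
  p <- cohort$patients
  labs_by_id <- unique(cohort$labs$id)
  keep <- rep(TRUE, nrow(p))
  tally <- stats::setNames(integer(length(rules)), rules)
  for (r in rules) {
    pass <- .eligibility_predicates[[r]](p, labs_by_id)
    removed <- keep & !pass
    tally[[r]] <- sum(removed)
    keep <- keep & pass
  }
  eligible <- new_cohort(p[keep, , drop = FALSE],
                         cohort$labs[cohort$labs$id %in% p$id[keep], , drop = FALSE])
  list(eligible = eligible, tally = tally, n_input = nrow(p))
}

#' Patient-selection flow summary
#'
#' Renders the eligibility result as the usual attrition flow (initial n,
#' per-rule exclusions, final analysed n), and optionally writes it as JSON.
#'
#' @param result The list returned by [apply_eligibility()].
#' @param json_path Optional path; when given the tally is written as JSON.
#' @return Character vector of flow lines, invisibly when printing.
#' @export
flow_summary <- function(result, json_path = NULL) {
  lines <- c(
    sprintf("Patients identified: %d", result$n_input),
    sprintf("  excluded by %-28s %d", paste0(names(result$tally), ":"), result$tally),
    sprintf("Analysed in final cohort: %d", nrow(result$eligible$patients))
  )
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(n_input = result$n_input, excluded = as.list(result$tally),
           n_final = nrow(result$eligible$patients)),
      json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  lines
}
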