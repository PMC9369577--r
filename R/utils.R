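#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

#' Analytes recognised by the package
#'
#' Serum analytes tracked in the pre-procedure window: total and direct
#' bilirubin, the transaminases, alkaline phosphatase, gamma-glutamyl
#' transferase, and lipase.
#'
#' @format Character vector of analyte codes.
#' @export
ANALYTES <- c("TBILI", "DBILI", "ALT", "AST", "ALP", "GGT", "LIPASE")

# legal reporting units per analyte; first entry is the canonical unit
.analyte_units <- list(
  TBILI  = c("umol/L", "mg/dL"),
  DBILI  = c("umol/L", "mg/dL"),
  ALT    = "U/L",
  AST    = "U/L",
  ALP    = "U/L",
  GGT    = "U/L",
  LIPASE = "U/L"
)

#' Round half away from zero
#'
#' Percentages in reports are rounded to one decimal with halves going away
#' from zero (so 73.95 prints as 74.0), unlike [base::round()]'s banker's
#' rounding. Internal computation is always at full precision.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Three-valued AND: unknown if ANY operand is unknown (even when another is
# FALSE). This is deliberately stricter than R's Kleene `&` so that a patient
# missing one analyte contributes to no combined-predictor model at all.
and3 <- function(...) {
  ops <- c(...)
  if (anyNA(ops)) NA else all(ops)
}

# Three-valued OR: true if any defined operand is true; unknown if none is
# true and at least one operand is unknown.
or3 <- function(...) {
  ops <- c(...)
  if (any(ops %in% TRUE)) TRUE else if (anyNA(ops)) NA else FALSE
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}
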