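#' EN689:1995 preliminary (screening) test
#'
#' Screening decision from the first 1 or 3 measurements of a SEG, taken
#' in sampling-date order. With a single measurement, compliance requires
#' the value to fall below 0.1 x OEL; with three measurements, all must
#' fall below 0.25 x OEL. Any single value above the OEL triggers
#' non-compliance immediately; anything in between is an uncertain
#' decision that defers to the statistical phase.
#'
#' Inequalities are strict on both sides: a value exactly at the screen
#' threshold, or exactly at the OEL, yields `uncertain`.
#'
#' @param values Numeric vector of 1 or 3 positive concentrations (mg/m3),
#'   the date-ordered preliminary subset (see
#'   [select_preliminary_subset()]).
#' @param oel An [oel_spec()] or a positive number.
#' @return A [compliance_decision()] with strategy `EN689_1995_PRELIM`.
#'   The `statistic` is the largest value relative to the OEL.
#' @examples
#' preliminary_1995(0.05, oel_spec(1))          # compliance
#' preliminary_1995(c(0.3, 0.2, 0.2), 1)        # uncertain
#' @export
preliminary_1995 <- function(values, oel) {
  limit <- oel_value(oel)
  check_prelim_values(values)
  n <- length(values)
  if (!n %in% c(1L, 3L))
    stop("EN689:1995 preliminary test requires 1 or 3 measurements",
         call. = FALSE)
  screen <- if (n == 1L) 0.10 else 0.25
  outcome <- screen_outcome(values, limit, screen)
  compliance_decision("EN689_1995_PRELIM", outcome,
                      statistic = max(values) / limit, n_used = n)
}

#' EN689:2018 preliminary (screening) test
#'
#' Screening decision from the first 3, 4 or 5 measurements of a SEG.
#' Compliance requires every value below a fraction of the OEL that
#' relaxes with sample size: 0.1 x OEL for three measurements, 0.15 x OEL
#' for four, 0.2 x OEL for five. Any value above the OEL is immediate
#' non-compliance; otherwise the decision is uncertain and more
#' measurements are needed for the statistical test.
#'
#' @inheritParams preliminary_1995
#' @param values Numeric vector of 3, 4 or 5 positive concentrations.
#' @return A [compliance_decision()] with strategy `EN689_2018_PRELIM`.
#' @examples
#' preliminary_2018(c(0.05, 0.05, 0.05), 1)             # compliance
#' preliminary_2018(c(0.19, 0.19, 0.19, 0.19, 0.19), 1) # compliance
#' @export
preliminary_2018 <- function(values, oel) {
  limit <- oel_value(oel)
  check_prelim_values(values)
  n <- length(values)
  if (!n %in% c(3L, 4L, 5L))
    stop("EN689:2018 preliminary test requires 3, 4 or 5 measurements",
         call. = FALSE)
  screen <- c(`3` = 0.10, `4` = 0.15, `5` = 0.20)[[as.character(n)]]
  outcome <- screen_outcome(values, limit, screen)
  compliance_decision("EN689_2018_PRELIM", outcome,
                      statistic = max(values) / limit, n_used = n)
}

# Shared screening logic: all below screen * OEL -> compliance; any above
# the OEL itself -> non-compliance; otherwise uncertain. Strict inequalities.
screen_outcome <- function(values, limit, screen) {
  if (all(values < screen * limit)) "compliance"
  else if (any(values > limit)) "non_compliance"
  else "uncertain"
}

check_prelim_values <- function(values) {
  if (!is.numeric(values) || length(values) == 0L ||
      any(!is.finite(values)) || any(values <= 0))
    stop("`values` must be positive finite concentrations", call. = FALSE)
  invisible(values)
}
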