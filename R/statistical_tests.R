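#' Fit a lognormal distribution to exposure measurements
#'
#' Computes the sample mean and standard deviation of the natural-log
#' concentrations (n - 1 denominator), together with the geometric mean
#' GM = exp(mean log) and geometric standard deviation GSD = exp(sd log).
#' Full-shift exposure concentrations within a SEG are conventionally
#' modelled as lognormal, and both EN689 statistical tests operate on
#' this fit.
#'
#' @param values Numeric vector of at least two positive concentrations
#'   (mg/m3).
#' @return An object of class `lognormal_fit` with fields `n`, `mean_log`,
#'   `sd_log`, `gm`, `gsd`.
#' @examples
#' fit_lognormal(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
#' @export
fit_lognormal <- function(values) {
  if (!is.numeric(values) || any(!is.finite(values)) || any(values <= 0))
    stop("`values` must be positive finite concentrations", call. = FALSE)
  n <- length(values)
  if (n < 2L)
    stop("at least two measurements are needed to fit a lognormal",
         call. = FALSE)
  logs <- log(values)
  m <- mean(logs)
  s <- stats::sd(logs)
  structure(list(n = n, mean_log = m, sd_log = s,
                 gm = exp(m), gsd = exp(s)),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("Lognormal fit: n = %d, GM = %.4g, GSD = %.4g\n",
              x$n, x$gm, x$gsd))
  invisible(x)
}

#' Plug-in exceedance probability
#'
#' Point estimate of the exceedance fraction: the probability that a
#' random full-shift exposure drawn from the fitted lognormal exceeds the
#' OEL, `1 - pnorm((log(OEL) - mean_log) / sd_log)`. When the fitted
#' spread is zero the distribution is degenerate at the GM, and the
#' probability is 0, 1 or 0.5 according to whether the GM is below, above
#' or exactly at the OEL.
#'
#' @param fit A `lognormal_fit` (see [fit_lognormal()]).
#' @param oel An [oel_spec()] or a positive number.
#' @return The exceedance probability, a number in \[0, 1\].
#' @export
exceedance_probability <- function(fit, oel) {
  stopifnot(inherits(fit, "lognormal_fit"))
  limit <- oel_value(oel)
  if (fit$sd_log == 0) {
    if (fit$gm < limit) return(0)
    if (fit$gm > limit) return(1)
    return(0.5)
  }
  stats::pnorm((log(limit) - fit$mean_log) / fit$sd_log,
               lower.tail = FALSE)
}

#' EN689:1995 statistical test (5% exceedance rule)
#'
#' Group compliance test on at least six measurements: the SEG is
#' compliant when the plug-in exceedance probability of the fitted
#' lognormal is strictly below 5%, non-compliant otherwise. This is the
#' 1995 scheme with the green/orange zoning removed, so the decision is
#' always binary. An exceedance of exactly 5% is read conservatively as
#' non-compliance.
#'
#' @inheritParams exceedance_probability
#' @return A [compliance_decision()] with strategy `EN689_1995_STAT`;
#'   `statistic` carries the exceedance probability.
#' @export
statistical_test_1995 <- function(fit, oel) {
  stopifnot(inherits(fit, "lognormal_fit"))
  if (fit$n < 6L)
    stop("the statistical test requires at least 6 measurements",
         call. = FALSE)
  p_exc <- exceedance_probability(fit, oel)
  compliance_decision("EN689_1995_STAT",
                      if (p_exc < 0.05) "compliance" else "non_compliance",
                      statistic = p_exc, n_used = fit$n)
}

#' One-sided normal tolerance factor
#'
#' Factor k such that `mean + k * sd` of a normal sample of size n is an
#' upper tolerance limit covering the true p-th quantile with confidence
#' gamma. Computed exactly from the non-central t distribution:
#' `k = qt(gamma, df = n - 1, ncp = qnorm(p) * sqrt(n)) / sqrt(n)`.
#' With the EN689:2018 defaults (p = 0.95, gamma = 0.70) this is the
#' UTL95,70 factor. k decreases with n towards `qnorm(p)`.
#'
#' @param n Sample size, at least 2.
#' @param p Percentile level covered (default 0.95).
#' @param gamma Confidence level (default 0.70).
#' @return An object of class `tolerance_factor` with fields `n`, `p`,
#'   `gamma`, `k`.
#' @examples
#' tolerance_factor(6)$k   # about 2.18
#' @export
tolerance_factor <- function(n, p = 0.95, gamma = 0.70) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("`n` must be an integer >= 2", call. = FALSE)
  stopifnot(p > 0, p < 1, gamma > 0, gamma < 1)
  k <- stats::qt(gamma, df = n - 1, ncp = stats::qnorm(p) * sqrt(n)) / sqrt(n)
  structure(list(n = as.integer(n), p = p, gamma = gamma, k = k),
            class = "tolerance_factor")
}

#' @export
print.tolerance_factor <- function(x, ...) {
  cat(sprintf("Tolerance factor k(n = %d, p = %.2f, gamma = %.2f) = %.4f\n",
              x$n, x$p, x$gamma, x$k))
  invisible(x)
}

#' Upper tolerance limit UTL95,70
#'
#' The EN689:2018 test statistic: `exp(mean_log + k(n) * sd_log)`, an
#' upper limit that exceeds the true 95th percentile of the underlying
#' lognormal exposure distribution with 70% confidence.
#'
#' @inheritParams exceedance_probability
#' @return The UTL in mg/m3.
#' @export
utl_95_70 <- function(fit) {
  stopifnot(inherits(fit, "lognormal_fit"))
  if (fit$n < 6L)
    stop("UTL95,70 requires at least 6 measurements", call. = FALSE)
  exp(fit$mean_log + tolerance_factor(fit$n)$k * fit$sd_log)
}

#' EN689:2018 statistical test (UTL95,70 rule)
#'
#' Group compliance test on at least six measurements: the SEG is
#' compliant when the upper tolerance limit of the 95th percentile at 70%
#' confidence falls strictly below the OEL, non-compliant otherwise.
#' Because k(n) exceeds the plain 95th-percentile z-score, this test is
#' uniformly more stringent than the 1995 5%-exceedance rule: a SEG
#' compliant here is always compliant there.
#'
#' @inheritParams exceedance_probability
#' @return A [compliance_decision()] with strategy `EN689_2018_STAT`;
#'   `statistic` carries the UTL.
#' @export
statistical_test_2018 <- function(fit, oel) {
  stopifnot(inherits(fit, "lognormal_fit"))
  if (fit$n < 6L)
    stop("the statistical test requires at least 6 measurements",
         call. = FALSE)
  limit <- oel_value(oel)
  utl <- utl_95_70(fit)
  compliance_decision("EN689_2018_STAT",
                      if (utl < limit) "compliance" else "non_compliance",
                      statistic = utl, n_used = fit$n)
}
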