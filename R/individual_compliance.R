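#' Between- and within-worker variance components
#'
#' One-way random-effects (ANOVA moment) decomposition of the natural-log
#' concentrations of a SEG by worker. The within-worker variance is the
#' pooled within-worker mean square (day-to-day variability); the
#' between-worker variance is the excess of the between-worker mean
#' square, scaled by the effective per-worker replication
#' `n0 = (N - sum(ni^2)/N) / (K - 1)` for K workers with ni measurements
#' each (the unbalanced-design correction). A negative moment estimate of
#' the between-worker variance is clamped to zero. With a single worker
#' no between-worker contrast exists and the between-worker variance is
#' set to zero.
#'
#' @param seg A `seg` object with at least six measurements and at least
#'   one worker measured repeatedly.
#' @return An object of class `variance_components` with fields `mu_log`
#'   (grand mean of logs), `sigma2_B`, `sigma2_W`, `n_workers`, `n_total`
#'   and `n0`.
#' @references Kromhout, Symanski and Rappaport (1993), Ann Occup Hyg 37,
#'   for the canonical between-/within-worker decomposition of
#'   occupational exposure data.
#' @export
variance_components <- function(seg) {
  stopifnot(inherits(seg, "seg"))
  if (seg$n_measurements < 6L)
    stop("variance decomposition requires at least 6 measurements",
         call. = FALSE)
  y <- log(seg$measurements$concentration)
  worker <- seg$measurements$worker_id
  counts <- table(worker)  # names sorted; align means to the same order
  ni <- as.vector(counts)
  if (all(ni < 2L))
    stop("no worker has repeated measurements; within-worker variance ",
         "is not estimable", call. = FALSE)
  N <- length(y)
  K <- length(ni)
  means <- tapply(y, worker, mean)
  grand <- mean(y)
  ssw <- sum((y - means[worker])^2)
  s2w <- ssw / (N - K)
  if (K == 1L) {
    n0 <- N
    s2b <- 0
  } else {
    mi <- as.vector(means[names(counts)])
    ssb <- sum(ni * (mi - grand)^2)
    msb <- ssb / (K - 1)
    n0 <- (N - sum(ni^2) / N) / (K - 1)
    s2b <- max(0, (msb - s2w) / n0)
  }
  structure(list(mu_log = grand, sigma2_B = s2b, sigma2_W = s2w,
                 n_workers = K, n_total = N, n0 = n0),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(paste0("Variance components (log scale): between = %.4g, ",
                     "within = %.4g\n  %d workers, %d measurements, ",
                     "n0 = %.3g\n"),
              x$sigma2_B, x$sigma2_W, x$n_workers, x$n_total, x$n0))
  invisible(x)
}

#' Fraction of workers exceeding the individual criterion
#'
#' Model-based estimate of theta, the fraction of SEG members whose
#' personal 95th percentile of daily exposure exceeds the OEL. Under the
#' random-effects lognormal model a worker with personal log-mean b has
#' 95th percentile `exp(b + z95 * sqrt(sigma2_W))`, and b is normal with
#' mean `mu_log` and variance `sigma2_B`, so
#' `theta = 1 - pnorm((log(OEL) - mu_log - z95 * sqrt(sigma2_W)) /
#' sqrt(sigma2_B))`. When the between-worker variance is zero all workers
#' share one distribution and theta degenerates to 0 or 1 according to
#' whether the common 95th percentile lies below the OEL.
#'
#' @param vc A `variance_components` object (see [variance_components()]).
#' @param oel An [oel_spec()] or a positive number.
#' @return theta, a probability in \[0, 1\].
#' @export
individual_theta <- function(vc, oel) {
  stopifnot(inherits(vc, "variance_components"))
  limit <- oel_value(oel)
  z95 <- stats::qnorm(0.95)
  p95_log <- vc$mu_log + z95 * sqrt(vc$sigma2_W)
  if (vc$sigma2_B == 0)
    return(if (p95_log >= log(limit)) 1 else 0)
  stats::pnorm((log(limit) - p95_log) / sqrt(vc$sigma2_B),
               lower.tail = FALSE)
}

#' BOHS-NVvA individual compliance test
#'
#' The individual compliance criterion: a SEG complies when more than 80%
#' of its members have at least 95% of their personal exposure
#' distribution below the OEL, i.e. when theta (the estimated fraction of
#' overexposed workers, [individual_theta()]) is strictly below 0.20.
#'
#' The individual criterion is only informative when workers genuinely
#' differ, so the test routes on the between-worker share of total
#' log-variance `rho_B = sigma2_B / (sigma2_B + sigma2_W)`: SEGs with
#' `rho_B >= 0.20` take the individual test; SEGs that are homogeneous
#' between workers (`rho_B < 0.20`) fall back to the group 5%-exceedance
#' test on the pooled lognormal fit. Either way the decision is labelled
#' strategy `BOHS_NVVA`.
#'
#' @param seg A `seg` object with at least six measurements and at least
#'   one worker with repeated measurements.
#' @param oel An [oel_spec()] or a positive number.
#' @return An object of class `individual_compliance_result` with fields
#'   `theta`, `rho_B`, `route` (`"individual_test"` or `"group_test"`),
#'   `vc` (the variance components) and `decision` (a
#'   [compliance_decision()]; its `statistic` is theta on the individual
#'   route and the pooled exceedance probability on the group route).
#' @export
bohs_nvva_test <- function(seg, oel) {
  vc <- variance_components(seg)
  limit <- oel_value(oel)
  total <- vc$sigma2_B + vc$sigma2_W
  rho_b <- if (total == 0) 0 else vc$sigma2_B / total
  theta <- individual_theta(vc, limit)
  if (rho_b >= 0.20) {
    route <- "individual_test"
    outcome <- if (theta < 0.20) "compliance" else "non_compliance"
    decision <- compliance_decision("BOHS_NVVA", outcome, statistic = theta,
                                    n_used = vc$n_total)
  } else {
    route <- "group_test"
    fit <- fit_lognormal(seg$measurements$concentration)
    p_exc <- exceedance_probability(fit, limit)
    outcome <- if (p_exc < 0.05) "compliance" else "non_compliance"
    decision <- compliance_decision("BOHS_NVVA", outcome, statistic = p_exc,
                                    n_used = vc$n_total)
  }
  structure(list(theta = theta, rho_B = rho_b, route = route, vc = vc,
                 decision = decision),
            class = "individual_compliance_result")
}

#' @export
print.individual_compliance_result <- function(x, ...) {
  cat(sprintf(paste0("BOHS-NVvA: rho_B = %.3f -> %s\n  theta = %.4g, ",
                     "decision: %s\n"),
              x$rho_B, x$route, x$theta, x$decision$outcome))
  invisible(x)
}

#' Sensitivity filter: SEGs with repeats for two or more workers
#'
#' Keeps only the SEGs in which at least two distinct workers were
#' measured repeatedly. Variance components estimated from a single
#' repeated worker rest on one within-worker contrast; this filter is the
#' sensitivity analysis that removes such SEGs.
#'
#' @param segs List of `seg` objects.
#' @return The subset of `segs` with at least two workers having two or
#'   more measurements each.
#' @export
sensitivity_filter <- function(segs) {
  Filter(function(seg) {
    sum(table(seg$measurements$worker_id) >= 2L) >= 2L
  }, segs)
}
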