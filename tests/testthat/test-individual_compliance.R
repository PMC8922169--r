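# Independent ANOVA route: mean squares from lm/anova, moment estimators
# assembled from them.
anova_oracle <- function(seg) {
  y <- log(seg$measurements$concentration)
  w <- factor(seg$measurements$worker_id)
  tab <- anova(lm(y ~ w))
  msb <- tab["w", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  ni <- as.vector(table(w))
  N <- length(y)
  K <- length(ni)
  n0 <- (N - sum(ni^2) / N) / (K - 1)
  list(mu_log = mean(y), sigma2_W = msw,
       sigma2_B = max(0, (msb - msw) / n0), n0 = n0)
}

test_that("variance components match the classical ANOVA mean squares", {
  set.seed(21)
  for (i in 1:20) {
    # unbalanced: 3-6 workers, 1-4 repeats each, at least one repeated
    reps <- pmax(1L, rpois(sample(3:6, 1), 1.5))
    if (all(reps < 2L)) reps[1] <- 2L
    while (sum(reps) < 6L) reps <- reps + 1L
    seg <- generate_seg(seg_spec("S", reps, mu_log = log(0.3),
                                 sigma2_B = 0.3, sigma2_W = 0.5,
                                 seed = 1000L + i))
    vc <- variance_components(seg)
    orc <- anova_oracle(seg)
    expect_equal(vc$mu_log, orc$mu_log, tolerance = 1e-12)
    expect_equal(vc$sigma2_W, orc$sigma2_W, tolerance = 1e-10)
    expect_equal(vc$sigma2_B, orc$sigma2_B, tolerance = 1e-10)
    expect_equal(vc$n0, orc$n0, tolerance = 1e-12)
    expect_equal(vc$n_total, seg$n_measurements)
  }
})

test_that("degenerate SEGs give the expected variance components", {
  # identical values within each worker: all variance is between workers
  seg <- make_seg(rep(c(0.2, 0.4, 0.8), each = 2),
                  worker = rep(1:3, each = 2))
  vc <- variance_components(seg)
  expect_equal(vc$sigma2_W, 0)
  expect_equal(vc$sigma2_B, var(log(c(0.2, 0.4, 0.8))) -
                 0)  # balanced, msw = 0: (m*var(means))/m
  expect_equal(vc$n0, 2)

  # all values equal: nothing varies
  flat <- variance_components(make_seg(rep(0.3, 6), worker = rep(1:3, 2)))
  expect_equal(flat$sigma2_B, 0)
  expect_equal(flat$sigma2_W, 0)

  # a negative moment estimate clamps to zero: workers identical in mean,
  # large within-worker scatter
  set.seed(2)
  noisy <- make_seg(exp(rnorm(12, log(0.3), 1)), worker = rep(1:2, 6))
  vc2 <- variance_components(noisy)
  expect_gte(vc2$sigma2_B, 0)

  # single worker: no between-worker contrast
  solo <- variance_components(make_seg(exp(rnorm(6, -1, 0.4)),
                                       worker = rep(1, 6)))
  expect_equal(solo$sigma2_B, 0)
  expect_gt(solo$sigma2_W, 0)
})

test_that("variance_components enforces its preconditions", {
  expect_error(variance_components(make_seg(c(0.1, 0.2, 0.3),
                                            worker = c(1, 1, 2))),
               "at least 6")
  expect_error(variance_components(make_seg(runif(6, 0.1, 0.5),
                                            worker = 1:6)),
               "repeated")
})

test_that("individual_theta matches its closed form and limits", {
  z95 <- qnorm(0.95)
  vc_at <- structure(list(mu_log = -z95 * sqrt(0.5), sigma2_B = 0.2,
                          sigma2_W = 0.5, n_workers = 10, n_total = 30,
                          n0 = 3), class = "variance_components")
  # group 95th percentile exactly at the OEL: half the workers exceed
  expect_equal(individual_theta(vc_at, 1), 0.5)

  vc0 <- vc_at
  vc0$sigma2_B <- 0
  vc0$mu_log <- -2
  expect_equal(individual_theta(vc0, 1), 0)  # common P95 below OEL
  vc0$mu_log <- -z95 * sqrt(0.5)             # common P95 at the OEL
  expect_equal(individual_theta(vc0, 1), 1)
})

test_that("theta increases with mu_log and sigma2_W", {
  base <- structure(list(mu_log = log(0.2), sigma2_B = 0.2, sigma2_W = 0.5,
                         n_workers = 10, n_total = 30, n0 = 3),
                    class = "variance_components")
  t0 <- individual_theta(base, 1)
  up_mu <- base; up_mu$mu_log <- base$mu_log + 0.3
  up_w <- base; up_w$sigma2_W <- base$sigma2_W + 0.3
  up_b <- base; up_b$sigma2_B <- base$sigma2_B + 0.3
  expect_gt(individual_theta(up_mu, 1), t0)
  expect_gt(individual_theta(up_w, 1), t0)
  # with the group P95 below the OEL, more heterogeneity -> more exceeders
  expect_gt(individual_theta(up_b, 1), t0)
})

test_that("bohs_nvva_test routes on the between-worker variance share", {
  # strong between-worker signal, workers far below the OEL: individual
  # route, compliant
  set.seed(31)
  gm_w <- exp(rnorm(8, log(0.05), sqrt(0.8)))
  seg_b <- make_seg(rep(gm_w, each = 3) * exp(rnorm(24, 0, 0.1)),
                    worker = rep(1:8, each = 3))
  res_b <- bohs_nvva_test(seg_b, 1)
  expect_gte(res_b$rho_B, 0.2)
  expect_identical(res_b$route, "individual_test")
  expect_equal(res_b$decision$statistic, res_b$theta)

  # same worker means near the OEL: individual route, non-compliant
  seg_hi <- make_seg(rep(gm_w, each = 3) * exp(rnorm(24, 0, 0.1)) * 30,
                     worker = rep(1:8, each = 3))
  res_hi <- bohs_nvva_test(seg_hi, 1)
  expect_identical(res_hi$route, "individual_test")
  expect_gte(res_hi$theta, 0.2)
  expect_identical(res_hi$decision$outcome, "non_compliance")

  # homogeneous workers: group route, decided by the pooled 5% exceedance
  seg_g <- generate_seg(seg_spec("G", rep(5, 8), mu_log = log(0.1),
                                 sigma2_B = 0, sigma2_W = 0.3, seed = 4))
  res_g <- bohs_nvva_test(seg_g, 1)
  expect_identical(res_g$route, "group_test")
  fit <- fit_lognormal(seg_g$measurements$concentration)
  expect_equal(res_g$decision$statistic, exceedance_probability(fit, 1))
  expect_identical(res_g$decision$outcome,
                   statistical_test_1995(fit, 1)$outcome)
  expect_identical(res_g$decision$strategy, "BOHS_NVVA")
})

test_that("sensitivity filter keeps SEGs with >= 2 repeated workers", {
  one_rep <- make_seg(runif(6, 0.1, 0.5), worker = c(1, 1, 2, 3, 4, 5))
  two_rep <- make_seg(runif(6, 0.1, 0.5), worker = c(1, 1, 2, 2, 3, 3))
  none <- make_seg(runif(6, 0.1, 0.5), worker = 1:6)
  kept <- sensitivity_filter(list(one_rep, two_rep, none))
  expect_length(kept, 1L)
  expect_identical(kept[[1]]$seg_id, two_rep$seg_id)
  expect_length(sensitivity_filter(list()), 0L)
})
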