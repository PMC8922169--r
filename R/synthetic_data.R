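# Run code with a private RNG stream: seeds, then restores whatever
# .Random.seed the caller had.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  code
}

# sample() that never falls into the 1:x scalar interpretation.
sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# Deterministic per-SEG sub-seed, kept inside 32-bit integer range so the
# k-th SEG of a study is reproducible independently of how many SEGs are
# generated.
seg_sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + as.numeric(k) * 97003) %% 2147483629)
}

#' Specification of one synthetic SEG
#'
#' Describes a similar exposure group to simulate under the
#' random-effects lognormal model: worker i gets a latent personal
#' log-mean `b_i ~ Normal(mu_log, sigma2_B)`, and measurement j of worker
#' i is `exp(b_i + e_ij)` with `e_ij ~ Normal(0, sigma2_W)`.
#'
#' @param seg_id SEG identifier.
#' @param repeats_per_worker Integer vector: number of measurements for
#'   each worker (length = number of workers).
#' @param mu_log Overall log-scale mean (log of the group GM).
#' @param sigma2_B Between-worker log-variance, >= 0.
#' @param sigma2_W Within-worker (day-to-day) log-variance, >= 0.
#' @param start_date First sampling date; measurements are dated on
#'   consecutive days.
#' @param seed Integer seed; identical specs generate identical SEGs.
#' @return An object of class `seg_spec`.
#' @export
seg_spec <- function(seg_id, repeats_per_worker, mu_log, sigma2_B, sigma2_W,
                     start_date = as.Date("2019-01-01"), seed = 1L) {
  repeats_per_worker <- as.integer(repeats_per_worker)
  if (length(repeats_per_worker) == 0L || any(repeats_per_worker < 1L))
    stop("`repeats_per_worker` must be positive counts", call. = FALSE)
  if (!is.finite(mu_log) || sigma2_B < 0 || sigma2_W < 0)
    stop("`mu_log` must be finite and the variances non-negative",
         call. = FALSE)
  structure(list(seg_id = as.character(seg_id),
                 n_workers = length(repeats_per_worker),
                 repeats_per_worker = repeats_per_worker,
                 mu_log = mu_log, sigma2_B = sigma2_B, sigma2_W = sigma2_W,
                 start_date = as.Date(start_date), seed = as.integer(seed)),
            class = "seg_spec")
}

#' Simulate one SEG
#'
#' Draws measurements for a SEG under the random-effects lognormal model
#' described in [seg_spec()]. Sampling dates are assigned on consecutive
#' days from `start_date` in generation order (workers in sequence, each
#' worker's repeats together). The global RNG state is left untouched.
#'
#' @param spec A [seg_spec()].
#' @return A `seg` object (see [build_segs()]).
#' @examples
#' spec <- seg_spec("A", rep(2, 5), mu_log = log(0.2),
#'                  sigma2_B = 0.3, sigma2_W = 0.6, seed = 42)
#' generate_seg(spec)
#' @export
generate_seg <- function(spec) {
  stopifnot(inherits(spec, "seg_spec"))
  with_seed(spec$seed, {
    b <- stats::rnorm(spec$n_workers, spec$mu_log, sqrt(spec$sigma2_B))
    worker <- rep(seq_len(spec$n_workers), spec$repeats_per_worker)
    n <- length(worker)
    e <- stats::rnorm(n, 0, sqrt(spec$sigma2_W))
    df <- data.frame(
      seg_id = spec$seg_id,
      worker_id = sprintf("%s_w%03d", spec$seg_id, worker),
      sample_date = spec$start_date + seq_len(n) - 1L,
      concentration = exp(b[worker] + e),
      stringsAsFactors = FALSE
    )
    new_seg(spec$seg_id, df)
  })
}

#' Default parameter ranges for simulated studies
#'
#' The defaults span group geometric means from well below to just under
#' the OEL of 1 mg/m3 (GM 0.02-0.8, drawn log-uniformly) and total
#' geometric standard deviations typical of within-SEG exposure data
#' (GSD 1.5-3.5), so a simulated study exercises all decision branches:
#' clearly compliant, uncertain and non-compliant SEGs. The share of
#' total log-variance attributed to differences between workers is drawn
#' uniformly from 0 to 0.5, bracketing the 20% routing threshold of the
#' individual compliance test. SEG sizes are drawn from `size_range`
#' unless `total_measurements` pins the study total, in which case sizes
#' are 6 plus a deterministic round-robin distribution of the surplus.
#'
#' @param gm_range Range of group geometric means (mg/m3), sampled
#'   log-uniformly.
#' @param gsd_range Range of total geometric standard deviations.
#' @param rho_b_range Range of the between-worker fraction of total
#'   log-variance.
#' @param size_range Range of per-SEG measurement counts (min >= 6).
#' @param total_measurements Optional exact total number of measurements
#'   across the study.
#' @return A list of class `study_parameters`.
#' @export
study_parameters <- function(gm_range = c(0.02, 0.8),
                             gsd_range = c(1.5, 3.5),
                             rho_b_range = c(0, 0.5),
                             size_range = c(6L, 8L),
                             total_measurements = NULL) {
  stopifnot(length(gm_range) == 2L, all(gm_range > 0),
            length(gsd_range) == 2L, all(gsd_range >= 1),
            length(rho_b_range) == 2L, all(rho_b_range >= 0),
            all(rho_b_range <= 1), length(size_range) == 2L,
            size_range[1] >= 6L)
  structure(list(gm_range = as.numeric(gm_range),
                 gsd_range = as.numeric(gsd_range),
                 rho_b_range = as.numeric(rho_b_range),
                 size_range = as.integer(size_range),
                 total_measurements = total_measurements),
            class = "study_parameters")
}

#' Simulate a multi-SEG exposure study
#'
#' Generates a full study of SEGs with the structure of a multi-site
#' exposure survey: every SEG has at least six measurements and exactly
#' `n_with_repeats` of the SEGs contain at least one worker measured
#' repeatedly (the remainder sample each worker once). Per-SEG parameters
#' are drawn from `params` (see [study_parameters()]). The generator is
#' deterministic given `seed`, and SEG k is driven by its own sub-stream,
#' so it does not change when `n_segs` does.
#'
#' @param n_segs Number of SEGs.
#' @param n_with_repeats Number of SEGs that contain repeated
#'   measurements of at least one worker; must not exceed `n_segs`.
#'   Repeats are given to the first `n_with_repeats` SEGs.
#' @param params A [study_parameters()] object.
#' @param seed Integer seed.
#' @return A list of `seg` objects of length `n_segs`.
#' @examples
#' study <- generate_study(10, 7, seed = 1)
#' sum(vapply(study, `[[`, TRUE, "has_repeats"))
#' @export
generate_study <- function(n_segs, n_with_repeats,
                           params = study_parameters(), seed = 1L) {
  stopifnot(inherits(params, "study_parameters"))
  if (!is.numeric(n_segs) || n_segs < 1 || n_segs != round(n_segs))
    stop("`n_segs` must be a positive integer", call. = FALSE)
  if (n_with_repeats < 0 || n_with_repeats > n_segs)
    stop("`n_with_repeats` must be between 0 and `n_segs`", call. = FALSE)
  sizes <- study_sizes(n_segs, params)
  lapply(seq_len(n_segs), function(k) {
    sub <- seg_sub_seed(seed, k)
    with_seed(sub, {
      size <- if (is.null(sizes)) {
        sample_one(params$size_range[1]:params$size_range[2])
      } else sizes[k]
      gm <- exp(stats::runif(1, log(params$gm_range[1]),
                             log(params$gm_range[2])))
      gsd <- stats::runif(1, params$gsd_range[1], params$gsd_range[2])
      rho <- stats::runif(1, params$rho_b_range[1], params$rho_b_range[2])
      s2_tot <- log(gsd)^2
      reps <- allocate_repeats(size, has_repeats = k <= n_with_repeats)
      spec <- seg_spec(sprintf("SEG%04d", k), reps,
                       mu_log = log(gm),
                       sigma2_B = rho * s2_tot,
                       sigma2_W = (1 - rho) * s2_tot,
                       start_date = as.Date("2019-01-01") + (k - 1L) * 7L,
                       seed = seg_sub_seed(sub, 1L))
      generate_seg(spec)
    })
  })
}

# Fixed per-SEG sizes when the study total is pinned: base 6 everywhere,
# surplus distributed one measurement at a time from SEG 1 onwards.
study_sizes <- function(n_segs, params) {
  total <- params$total_measurements
  if (is.null(total)) return(NULL)
  extra <- total - 6L * n_segs
  if (extra < 0)
    stop("`total_measurements` too small for ", n_segs,
         " SEGs of at least 6 measurements", call. = FALSE)
  base <- extra %/% n_segs
  remainder <- extra %% n_segs
  6L + base + as.integer(seq_len(n_segs) <= remainder)
}

# Splits `size` measurements among workers. With repeats: fewer workers
# than measurements, surplus measurements assigned to random workers so at
# least one worker has >= 2. Without: one measurement per worker.
allocate_repeats <- function(size, has_repeats) {
  if (!has_repeats) return(rep(1L, size))
  n_workers <- sample_one(max(2L, ceiling(size / 2)):(size - 1L))
  reps <- rep(1L, n_workers)
  surplus <- size - n_workers
  extra <- table(sample(seq_len(n_workers), surplus, replace = TRUE))
  reps[as.integer(names(extra))] <- reps[as.integer(names(extra))] +
    as.integer(extra)
  reps
}
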