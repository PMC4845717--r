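.checkStrata <- function(strata) {
  need <- c("pop_count", "sample_size", "new_diag")
  if (!all(need %in% names(strata)))
    stop("schema error: strata need pop_count, sample_size, new_diag",
         call. = FALSE)
  if (any(strata$new_diag < 0 | strata$new_diag > strata$sample_size))
    stop("input error: new_diag must lie in [0, sample_size]", call. = FALSE)
  if (any(strata$sample_size == 0 & strata$pop_count > 0))
    stop("missing-sample error: stratum with population but no sample",
         call. = FALSE)
  strata
}

# Run one batch of simulated uplift replicates. Draws are consumed in
# stratum order (all replicates for stratum 1, then stratum 2, ...), then
# the prevalence draws, so a fixed seed yields bit-identical output.
.upliftReplicates <- function(strata, D, N, n_sims, simulate_prevalence) {
  new_mat <- matrix(0, nrow = n_sims, ncol = nrow(strata))
  for (s in seq_len(nrow(strata))) {
    n_s <- strata$sample_size[s]
    p_s <- strata$new_diag[s] / n_s
    k_star <- stats::rbinom(n_sims, n_s, p_s)
    new_mat[, s] <- k_star / n_s
  }
  if (simulate_prevalence) {
    if (is.null(N) || is.na(N))
      stop("input error: pop_total required when simulating prevalences",
           call. = FALSE)
    w_mat <- matrix(0, nrow = n_sims, ncol = nrow(strata))
    for (s in seq_len(nrow(strata)))
      w_mat[, s] <- stats::rbinom(n_sims, N, strata$pop_count[s] / N)
    D_star <- pmax(stats::rbinom(n_sims, N, D / N), 1L)
    expected_new <- rowSums(new_mat * w_mat)
  } else {
    D_star <- rep(D, n_sims)
    expected_new <- as.numeric(new_mat %*% strata$pop_count)
  }
  list(expected_new = expected_new, D_star = D_star)
}

#' Stratified weighted point estimate of diagnostic-yield uplift
#'
#' Projects the per-stratum re-diagnosis yields observed in a sequenced
#' subsample onto the referral population: the expected number of new
#' diagnoses is the stratum-size-weighted sum of the sample yields,
#' \eqn{\sum_s N_s k_s / n_s}, and the uplift is that count as a percentage
#' of the baseline number of diagnoses (relative uplift) or, with
#' \code{absolute = TRUE}, as percentage points of absolute yield over the
#' whole population.
#'
#' @param strata data.frame with columns pop_count (stratum size in the
#'   referral population), sample_size (patients re-sequenced) and new_diag
#'   (of those, patients gaining a diagnosis); see \code{\link{readStrata}}.
#' @param baseline_diagnosed Number of patients diagnosed by the baseline
#'   assay (must be > 0).
#' @param pop_total Referral-population size (required for
#'   \code{absolute}).
#' @param absolute Report percentage-point uplift instead of percent of
#'   baseline diagnoses.
#' @return An \linkS4class{UpliftEstimate} with CI fields NA.
#' @examples
#' pointUplift(data.frame(pop_count = 281, sample_size = 33, new_diag = 11),
#'             baseline_diagnosed = 281)
#' @export
pointUplift <- function(strata, baseline_diagnosed, pop_total = NULL,
                        absolute = FALSE) {
  strata <- .checkStrata(strata)
  if (baseline_diagnosed <= 0)
    stop("undefined-uplift error: baseline_diagnosed must be > 0",
         call. = FALSE)
  expected_new <- sum(strata$pop_count * strata$new_diag /
                        strata$sample_size)
  denom <- if (absolute) {
    if (is.null(pop_total))
      stop("input error: pop_total required for absolute uplift",
           call. = FALSE)
    pop_total
  } else baseline_diagnosed
  methods::new("UpliftEstimate", point = 100 * expected_new / denom,
               ciLow = NA_real_, ciHigh = NA_real_,
               expectedNew = expected_new, nSims = NA_integer_,
               seed = NA_integer_, absolute = absolute,
               replicates = numeric(0))
}

#' Simulation-based confidence interval for the uplift estimate
#'
#' Parametric-bootstrap percentile interval: each replicate redraws the
#' per-stratum re-diagnosis counts from \eqn{Binomial(n_s, k_s/n_s)} and,
#' when \code{simulate_prevalence} is TRUE (the default), also redraws the
#' stratum prevalences \eqn{Binomial(N, N_s/N)} and the baseline diagnosis
#' count \eqn{Binomial(N, D/N)}, propagating the sampling uncertainty of
#' every estimated proportion; the CI bounds are linear-interpolation
#' empirical quantiles of the replicate uplift distribution. With a fixed
#' seed the result is bit-identical across runs.
#'
#' @inheritParams pointUplift
#' @param n_sims Number of simulation replicates (default 10000).
#' @param ci Percentile bounds, default \code{c(2.5, 97.5)}.
#' @param seed Integer RNG seed; the global RNG state is restored on exit.
#' @param simulate_prevalence Also simulate stratum prevalences and the
#'   baseline diagnosis count (requires \code{pop_total}).
#' @return An \linkS4class{UpliftEstimate} with CI bounds, the replicate
#'   vector, simulation count and seed recorded.
#' @examples
#' est <- simulateCI(data.frame(pop_count = 281, sample_size = 33,
#'   new_diag = 11), baseline_diagnosed = 281, n_sims = 1000, seed = 1,
#'   simulate_prevalence = FALSE)
#' c(est@ciLow, est@ciHigh)
#' @export
simulateCI <- function(strata, baseline_diagnosed, pop_total = NULL,
                       n_sims = 10000, ci = c(2.5, 97.5), seed = 1,
                       simulate_prevalence = TRUE, absolute = FALSE) {
  if (n_sims < 2) stop("CI undefined error: n_sims must be >= 2",
                       call. = FALSE)
  stopifnot(length(ci) == 2L, ci[1] >= 0, ci[2] <= 100, ci[1] < ci[2])
  point <- pointUplift(strata, baseline_diagnosed, pop_total, absolute)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  rep_ <- .upliftReplicates(strata, baseline_diagnosed, pop_total,
                            as.integer(n_sims), simulate_prevalence)
  denom <- if (absolute) rep(pop_total, length(rep_$expected_new))
           else rep_$D_star
  replicates <- 100 * rep_$expected_new / denom
  q <- stats::quantile(replicates, probs = ci / 100, type = 7, names = FALSE)
  methods::new("UpliftEstimate", point = point@point, ciLow = q[1L],
               ciHigh = q[2L], expectedNew = point@expectedNew,
               nSims = as.integer(n_sims), seed = as.integer(seed),
               absolute = absolute, replicates = replicates)
}

#' Empirical coverage of the simulated confidence interval
#'
#' Validation harness for the interval method: repeatedly generates
#' stratified samples from a known truth (per-stratum true yields), runs
#' \code{\link{simulateCI}} on each, and reports the fraction of runs whose
#' interval contains the true uplift.
#'
#' @param strata data.frame with columns pop_count, sample_size and
#'   true_yield (per-stratum true re-diagnosis probability).
#' @param baseline_diagnosed,pop_total As in \code{\link{pointUplift}}.
#' @param n_experiments Number of simulated studies.
#' @param n_sims Replicates per confidence interval.
#' @param ci Percentile bounds.
#' @param seed Integer RNG seed.
#' @param simulate_prevalence Passed to \code{\link{simulateCI}}; FALSE by
#'   default so that coverage is assessed for the yield-sampling model that
#'   generated the data.
#' @return Numeric proportion of intervals covering the true uplift.
#' @export
coverageCheck <- function(strata, baseline_diagnosed, pop_total = NULL,
                          n_experiments = 200, n_sims = 2000,
                          ci = c(2.5, 97.5), seed = 1,
                          simulate_prevalence = FALSE) {
  stopifnot(all(c("pop_count", "sample_size", "true_yield") %in%
                  names(strata)))
  true_uplift <- 100 * sum(strata$pop_count * strata$true_yield) /
    baseline_diagnosed
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_experiments)
  covered <- vapply(seq_len(n_experiments), function(e) {
    obs <- strata
    obs$new_diag <- stats::rbinom(nrow(strata), strata$sample_size,
                                  strata$true_yield)
    est <- simulateCI(obs, baseline_diagnosed, pop_total, n_sims = n_sims,
                      ci = ci, seed = sub_seeds[e],
                      simulate_prevalence = simulate_prevalence)
    est@ciLow <= true_uplift && true_uplift <= est@ciHigh
  }, logical(1))
  mean(covered)
}
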