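# Independent oracles used across the suite. They never call the package's
# estimators: the binary ROC oracle counts cases and controls directly, and
# the Cox oracle maximizes the written partial likelihood on a grid.

# Empirical (binary) sensitivity/specificity at thresholds, for
# censoring-free data dichotomized at a horizon.
oracle_binary_se_sp <- function(marker, case, thresholds) {
  list(se = vapply(thresholds, function(c) mean(marker[case] > c), 0),
       sp = vapply(thresholds, function(c) mean(marker[!case] <= c), 0))
}

# Pairwise-comparison AUC (ties count 1/2) - the classical U-statistic.
oracle_binary_auc <- function(marker, case) {
  mc <- marker[case]; mn <- marker[!case]
  (sum(outer(mc, mn, ">")) + 0.5 * sum(outer(mc, mn, "=="))) /
    (length(mc) * length(mn))
}

# Log partial likelihood for a single covariate, Breslow form; on data with
# untied event times this coincides with the Efron form the package fits.
oracle_partial_loglik <- function(beta, time, event, z) {
  sum(vapply(which(event == 1L), function(i) {
    risk <- time >= time[i]
    beta * z[i] - log(sum(exp(beta * z[risk])))
  }, 0))
}

# Brute-force 1-D maximizer: coarse grid then golden-section refinement.
oracle_cox_beta <- function(time, event, z, lim = 10) {
  grid <- seq(-lim, lim, by = 0.01)
  ll <- vapply(grid, oracle_partial_loglik, 0, time = time, event = event,
               z = z)
  b0 <- grid[which.max(ll)]
  stats::optimize(oracle_partial_loglik, c(b0 - 0.02, b0 + 0.02),
                  time = time, event = event, z = z,
                  maximum = TRUE, tol = 1e-9)$maximum
}

# Small random censoring-free cohort with untied event times.
rand_uncensored_cohort <- function(n, seed) {
  set.seed(seed)
  cohort(time = sort(sample(seq(1, 100, by = 0.5), n)), event = rep(1L, n),
         rila = runif(n, 1, 99), tobacco = rbinom(n, 1, 0.4),
         ht = rbinom(n, 1, 0.7))
}

# Random right-censored cohort (exponential times, uniform censoring).
rand_censored_cohort <- function(n, seed, cens_rate = 0.25) {
  set.seed(seed)
  tev <- rexp(n, 0.1)
  tcen <- rexp(n, 0.1 * cens_rate / (1 - cens_rate))
  cohort(time = pmax(pmin(tev, tcen), 1e-3),
         event = as.integer(tev <= tcen),
         rila = runif(n, 1, 99), tobacco = rbinom(n, 1, 0.4),
         ht = rbinom(n, 1, 0.7))
}

# Frozen instance with censoring concentrated among high-marker subjects;
# drives the Kaplan-Meier estimator of Se/Sp out of [0, 1] at horizon 6
# (verified numerically when the instance was constructed).
km_violation_instance <- function() {
  list(marker = c(1, 6, 11, 5, 3, 2, 10, 7, 4, 9, 8, 12),
       time = c(7, 6.6, 3.9, 1.5, 1.4, 2.2, 2.7, 1.3, 8.3, 6.1, 7.8, 3.8),
       event = c(1L, 0L, 0L, 1L, 1L, 0L, 0L, 0L, 1L, 0L, 0L, 1L),
       horizon = 6)
}
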