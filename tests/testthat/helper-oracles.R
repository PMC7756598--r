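## Independent oracles: brute-force enumeration over the full outcome grid,
## kept deliberately separate from the package's convolution /
## meet-in-the-middle code paths.

brute_force_dist <- function(w, phi0) {
  m <- length(w)
  grid <- as.matrix(expand.grid(rep(list(0:1), m)))
  k <- rowSums(grid)
  list(t = as.vector(grid %*% w), pr = phi0^k * (1 - phi0)^(m - k))
}

brute_force_pvalue <- function(w, phi0, t_obs, tol = 1e-9) {
  d <- brute_force_dist(w, phi0)
  sum(d$pr[d$t >= t_obs - tol])
}

## random valid correlation matrix for property loops
random_test_cor <- function(m) random_correlation(m)

## cluster-aware Monte-Carlo SE for simulate_* results (the estimator is a
## mean of per-matrix rates, so between-matrix variation contributes)
cluster_se <- function(sim) {
  r <- sim$per_matrix_rates
  stats::sd(r) / sqrt(length(r))
}
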