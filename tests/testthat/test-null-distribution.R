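test_that("enumerated null distribution matches brute-force enumeration", {
  set.seed(31)
  for (m in c(3, 6, 9)) {
    for (phi0 in c(0.3, 0.5, 0.8)) {
      w <- compute_weights(random_test_cor(m))
      d <- exact_null_distribution(w, phi0)
      oracle <- brute_force_dist(w$w, phi0)
      # same probability mass at every distinct statistic value
      o <- order(oracle$t)
      grp <- cumsum(c(TRUE, diff(oracle$t[o]) > 1e-9))
      expect_equal(d$support, oracle$t[o][!duplicated(grp)], tolerance = 1e-12)
      expect_equal(d$probs, as.vector(rowsum(oracle$pr[o], grp)),
                   tolerance = 1e-12)
    }
  }
})

test_that("enumerated pmf conserves mass, mean and variance", {
  set.seed(32)
  for (m in c(4, 8, 12, 15)) {
    phi0 <- runif(1, 0.2, 0.8)
    w <- compute_weights(random_test_cor(m))
    d <- exact_null_distribution(w, phi0)
    expect_equal(sum(d$probs), 1, tolerance = 1e-12)
    mu <- sum(d$support * d$probs)
    v <- sum(d$support^2 * d$probs) - mu^2
    expect_equal(mu, phi0 * w$W, tolerance = 1e-10)
    expect_equal(v, phi0 * (1 - phi0) * w$sumsq, tolerance = 1e-10)
    expect_true(all(d$support >= -1e-12 & d$support <= w$W + 1e-12))
  }
})

test_that("independent and perfectly-dependent cases reduce to the binomial", {
  # C = I: T ~ Binomial(m, phi0)
  d <- exact_null_distribution(compute_weights(diag(5)), 0.4)
  expect_equal(d$support, 0:5)
  expect_equal(d$probs, dbinom(0:5, 5, 0.4), tolerance = 1e-14)
  expect_equal(exact_pvalue(3, d), pbinom(2, 5, 0.4, lower.tail = FALSE),
               tolerance = 1e-14)
  # C = J: support {0, 1/m, ..., 1} with binomial masses
  dj <- exact_null_distribution(compute_weights(matrix(1, 6, 6)), 0.7)
  expect_equal(dj$support, (0:6) / 6, tolerance = 1e-12)
  expect_equal(dj$probs, dbinom(0:6, 6, 0.7), tolerance = 1e-12)
  # p-value at t equals the binomial tail at m * t
  expect_equal(exact_pvalue(4 / 6, dj), pbinom(3, 6, 0.7, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("equal-weight m = 6 chance null gives uniform 1/64 outcome probabilities", {
  d <- exact_null_distribution(rep(1, 6), 0.5)
  # every one of the 2^6 prediction vectors carries probability 0.015625;
  # collapsed by number correct these are the binomial masses
  expect_equal(d$probs, choose(6, 0:6) * 0.015625, tolerance = 1e-14)
  expect_equal(dbinom(3, 6, 0.5), 0.3125)
})

test_that("exact p-values are inclusive upper tails and monotone", {
  set.seed(33)
  w <- compute_weights(random_test_cor(7))
  d <- exact_null_distribution(w, 0.45)
  expect_equal(exact_pvalue(0, d), 1)
  expect_equal(exact_pvalue(-5, d), 1)
  expect_equal(exact_pvalue(w$W + 1, d), 0)
  # observed value included in the tail ("as or more extreme")
  t5 <- d$support[5]
  expect_equal(exact_pvalue(t5, d), sum(d$probs[5:length(d$probs)]),
               tolerance = 1e-12)
  # non-increasing in t_obs
  grid <- seq(-0.5, w$W + 0.5, length.out = 60)
  pv <- vapply(grid, exact_pvalue, numeric(1), dist = d)
  expect_true(all(diff(pv) <= 1e-12))
  # all-correct record at equal weights: binomial feasibility bound
  d5 <- exact_null_distribution(rep(1, 5), 0.5)
  expect_equal(exact_pvalue(5, d5), 0.03125)
})

test_that("meet-in-the-middle tail equals the enumerated distribution's tail", {
  set.seed(34)
  for (m in c(5, 8, 11)) {
    phi0 <- runif(1, 0.25, 0.75)
    w <- compute_weights(random_test_cor(m))
    d <- exact_null_distribution(w, phi0)
    for (t in c(0, sample(d$support, 5), w$W)) {
      expect_equal(predtest:::.tail_prob(w, phi0, t), exact_pvalue(t, d),
                   tolerance = 1e-12)
      expect_equal(predtest:::.tail_prob(w, phi0, t, upper = FALSE),
                   sum(d$probs[d$support <= t + 1e-9]), tolerance = 1e-12)
    }
  }
})

test_that("exact p-value agrees with a 200,000-draw Monte-Carlo oracle", {
  set.seed(35)
  nsim <- 200000
  for (m in c(6, 10, 12)) {
    phi0 <- runif(1, 0.3, 0.7)
    w <- compute_weights(random_test_cor(m))
    t_obs <- sum(w$w * rbinom(m, 1, 0.6))
    p_exact <- predtest:::.tail_prob(w, phi0, t_obs)
    draws <- matrix(rbinom(nsim * m, 1, phi0), nsim, m)
    p_mc <- mean(as.vector(draws %*% w$w) >= t_obs - 1e-9)
    se <- sqrt(p_mc * (1 - p_mc) / nsim)
    expect_lt(abs(p_exact - p_mc), 3 * se + 1e-12)
  }
})

test_that("normal approximation: anchor points, monotonicity, degenerate input", {
  w <- compute_weights(random_correlation(10, seed = 36))
  mu <- 0.5 * w$W
  sigma <- sqrt(0.25 * w$sumsq)
  expect_equal(normal_pvalue(mu, w, 0.5), 0.5)
  expect_equal(normal_pvalue(mu + qnorm(0.95) * sigma, w, 0.5), 0.05,
               tolerance = 1e-12)
  grid <- seq(0, w$W, length.out = 40)
  pv <- vapply(grid, normal_pvalue, numeric(1), w = w, phi0 = 0.5)
  expect_true(all(diff(pv) < 0))
  expect_error(normal_pvalue(1, w, 0), "phi0")
  expect_error(normal_pvalue(Inf, w, 0.5), "finite")
})

test_that("enumeration refuses m beyond the cap and points to the approximation", {
  w <- rep(0.8, 26)
  expect_error(exact_null_distribution(w, 0.5), "normal approximation")
})
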