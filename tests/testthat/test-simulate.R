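test_that("perfect prediction of large effects is always detected", {
  r <- simulate_power(m = 6, n_per_group = 50, delta = rep(3, 6),
                      phi_true = 1, n_matrices = 5, n_reps = 40, seed = 81)
  # all predictions and all observed signs correct: T_m = W, tail 0.5^6
  expect_equal(r$rejection_rate, 1)
})

test_that("type-I error stays at or below nominal with coverage by MC error", {
  r <- simulate_type1(m = 6, n_per_group = 20, scenario = "const", base = 1,
                      n_matrices = 10, n_reps = 60, seed = 82)
  se <- sqrt(max(r$rejection_rate, 0.01) * 0.99 / r$total_reps)
  expect_lte(r$rejection_rate, 0.05 + 3 * se)
  # tiny effects starve the test: type-I near zero for the spike scenario
  rs <- simulate_type1(m = 6, n_per_group = 10, scenario = "spike",
                       n_matrices = 10, n_reps = 60, seed = 83)
  expect_lt(rs$rejection_rate, r$rejection_rate + 0.02)
})

test_that("power rises with the true predictive ability", {
  lo <- simulate_power(m = 16, n_per_group = 20, scenario = "const",
                       phi_true = 0.6, n_matrices = 8, n_reps = 60, seed = 84)
  hi <- simulate_power(m = 16, n_per_group = 20, scenario = "const",
                       phi_true = 0.95, n_matrices = 8, n_reps = 60, seed = 84)
  expect_gt(hi$rejection_rate, lo$rejection_rate + 0.2)
})

test_that("simulation results are reproducible and carry coherent MC errors", {
  a <- simulate_power(m = 6, n_per_group = 10, scenario = "const",
                      phi_true = 0.8, n_matrices = 4, n_reps = 30, seed = 85)
  b <- simulate_power(m = 6, n_per_group = 10, scenario = "const",
                      phi_true = 0.8, n_matrices = 4, n_reps = 30, seed = 85)
  expect_identical(a$rejection_rate, b$rejection_rate)
  expect_identical(a$per_matrix_rates, b$per_matrix_rates)
  expect_equal(a$mc_se,
               sqrt(a$rejection_rate * (1 - a$rejection_rate) / a$total_reps),
               tolerance = 1e-12)
  expect_error(simulate_power(m = 30, n_per_group = 10, scenario = "const",
                              phi_true = 0.8, method = "exact"),
               "enumeration cap")
})

test_that("sensitivity: sample-correlation weights converge to true-weight decisions", {
  # huge estimation sample: weights coincide, agreement is total
  s <- simulate_sensitivity(m_grid = 10, phi_grid = 0.6, n = 5000,
                            n_reps = 25, seed = 86)
  expect_equal(s$average, 100)
  # m = 5 at phi0 = 0.7: the null is never rejectable, so decisions
  # trivially agree
  s5 <- simulate_sensitivity(m_grid = 5, phi_grid = c(0.5, 0.9), n = 10,
                             phi0 = 0.7, n_reps = 40, seed = 87)
  expect_true(all(s5$agreement == 100))
  expect_gt(minimum_required_m(0.7, 0.05), 5)
})

test_that("GMAE is non-negative and vanishes against the reference itself", {
  g <- gmae_study(m_grid = c(10, 20), phi0_grid = c(0.5, 0.9),
                  n_matrices = 3, n_pred_sets = 200, seed = 88)
  expect_true(all(g$gmae >= 0))
  expect_true(all(g$gmae < 0.2))
  # exact reference at small m isolates the true approximation error,
  # which is below the sampled-reference estimate's Monte-Carlo floor
  ge <- gmae_study(m_grid = 20, phi0_grid = 0.5, n_matrices = 3,
                   n_pred_sets = 200, reference = "exact", seed = 88)
  expect_true(all(ge$gmae >= 0))
})
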