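test_that("worked ASL example: statistic 1.74, fail to reject at alpha 0.05", {
  ex <- asl_example()
  res <- prediction_test(weights = ex$weights, outcomes = ex$outcomes,
                         phi0 = 0.5, alpha = 0.05)
  expect_equal(res$statistic, 1.74, tolerance = 1e-12)
  expect_false(res$reject)
  expect_identical(res$method, "exact")
  # outcomes recomputed from the published mean differences agree
  p <- evaluate_predictions(ex$effects, ex$predictions)
  expect_equal(as.integer(p), unname(ex$outcomes))
  # enumeration over the published rounded weights gives 19/64
  expect_equal(res$p.value, 19 / 64, tolerance = 1e-12)
})

test_that("data-driven paths reproduce the manual computation", {
  set.seed(51)
  C <- random_test_cor(5)
  d <- make_dataset(C, delta = c(1, 1, -1, 1, -1), n = 40,
                    design = "two-group", seed = 52)
  preds <- c(1, 1, -1, 1, -1)
  res <- prediction_test(data = d, predictions = preds, design = "two-group")
  # manual recomputation
  g <- d$group
  X <- as.matrix(d[setdiff(names(d), "group")])
  eff <- colMeans(X[g == 2, ]) - colMeans(X[g == 1, ])
  centred <- rbind(sweep(X[g == 1, ], 2, colMeans(X[g == 1, ])),
                   sweep(X[g == 2, ], 2, colMeans(X[g == 2, ])))
  w <- compute_weights(cor(centred))
  expect_equal(res$statistic,
               sum(w$w[sign(eff) == preds]), tolerance = 1e-12)
  expect_equal(res$W, w$W, tolerance = 1e-12)
  expect_equal(res$n, 80L)

  # paired design: effects are column means of the differences
  dp <- make_dataset(C, delta = rep(0.8, 5), n = 30, design = "paired",
                     seed = 53)
  rp <- prediction_test(data = dp, predictions = rep(1, 5))
  expect_equal(rp$statistic,
               sum(compute_weights(cor(as.matrix(dp)))$w[colMeans(dp) > 0]),
               tolerance = 1e-12)
})

test_that("decision rule: the T_m >= 1 gate blocks low-weight rejections", {
  # nearly collinear endpoints: 5 of 6 correct but under one effective endpoint
  C <- matrix(0.99, 6, 6); diag(C) <- 1
  out <- c(1, 1, 1, 1, 1, 0)
  gated <- prediction_test(correlation = C, outcomes = out, phi0 = 0.01)
  expect_lte(gated$p.value, 0.05)
  expect_lt(gated$statistic, 1)
  expect_false(gated$reject)
  ungated <- prediction_test(correlation = C, outcomes = out, phi0 = 0.01,
                             require_t_ge_1 = FALSE)
  expect_true(ungated$reject)
  # perfect dependence: any single wrong prediction forbids rejection
  wj <- compute_weights(matrix(1, 4, 4))
  t_wrong <- test_statistic(c(1, 1, 1, 0), wj)
  expect_lt(t_wrong, 1)
})

test_that("method selection and validation errors", {
  set.seed(54)
  C <- random_test_cor(6)
  out <- rbinom(6, 1, 0.5)
  expect_identical(prediction_test(correlation = C, outcomes = out)$method,
                   "exact")
  C22 <- random_test_cor(22)
  r22 <- prediction_test(correlation = C22, outcomes = rbinom(22, 1, 0.5))
  expect_identical(r22$method, "normal")
  # exact and normal agree reasonably at moderate m
  r_ex <- prediction_test(correlation = C22, outcomes = r22$outcomes,
                          method = "exact", max_exact_m = 25)
  expect_lt(abs(r_ex$p.value - r22$p.value), 0.05)

  expect_error(prediction_test(correlation = matrix(1, 1, 1), outcomes = 1),
               "at least 2")
  expect_error(prediction_test(correlation = C, outcomes = out, phi0 = 1.2),
               "phi0")
  expect_error(prediction_test(correlation = C, outcomes = out[1:3]),
               "length mismatch")
  expect_error(prediction_test(outcomes = out), "supply either")
  expect_error(prediction_test(data = data.frame(a = 1:5, b = 1:5)),
               "predictions are required")
})

test_that("feasibility rule: smallest m with phi0^m <= alpha", {
  expect_identical(minimum_required_m(0.5, 0.05), 5L)
  expect_identical(minimum_required_m(0.6, 0.05), 6L)
  expect_identical(minimum_required_m(0.7, 0.05), 9L)
  expect_identical(minimum_required_m(0.9, 0.05), 29L)
  # hand check near the boundary: 0.8^13 > 0.05 >= 0.8^14
  expect_identical(minimum_required_m(0.8, 0.05), 14L)
  expect_gt(0.8^13, 0.05)
  expect_lte(0.8^14, 0.05)
  # the rule is exact: at the returned m only a perfect record rejects
  for (phi0 in c(0.5, 0.65, 0.8)) {
    m <- minimum_required_m(phi0)
    expect_lte(phi0^m, 0.05)
    expect_gt(phi0^(m - 1), 0.05)
  }
})
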