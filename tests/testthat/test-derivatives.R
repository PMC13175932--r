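test_that("constant signals differentiate to zero under every method", {
  x <- rep(3.7, 60)
  expect_equal(differentiate(x, 0.1, derivative_policy("finite_difference")),
               rep(0, 60))
  expect_equal(tvregdiff(x, 0.1, alpha = 0.1), rep(0, 60), tolerance = 1e-8)
})

test_that("finite differences are exact on polynomials of degree <= 2 inside", {
  t <- seq(0, 5, 0.1)
  d <- differentiate(2 * t, 0.1, derivative_policy("finite_difference"))
  expect_equal(d, rep(2, length(t)), tolerance = 1e-12)
  x <- 1 + 0.5 * t - 3 * t^2
  d2 <- differentiate(x, 0.1, derivative_policy("finite_difference"))
  inner <- 2:(length(t) - 1)
  expect_equal(d2[inner], (0.5 - 6 * t)[inner], tolerance = 1e-10)
})

test_that("TV-regularised differentiation tracks a smooth derivative", {
  t <- seq(0, 2 * pi, 0.01)
  u <- tvregdiff(sin(t), 0.01, alpha = 1e-4, iterations = 100)
  central <- t > 0.3 * max(t) & t < 0.7 * max(t)
  # documented tolerance for the central 40% of the window
  expect_lt(max(abs(u - cos(t))[central]), 0.05)
})

test_that("tvregdiff is invariant to adding a constant to the signal", {
  set.seed(1)
  x <- sin(seq(0, 3, 0.05)) + rnorm(61, 0, 0.01)
  expect_equal(tvregdiff(x, 0.05, 0.01), tvregdiff(x + 42, 0.05, 0.01),
               tolerance = 1e-9)
})

test_that("differentiation guards its preconditions", {
  expect_error(differentiate(1:4, 0.1), "5 samples")
  expect_error(tvregdiff(1:3, 0.1, 0.1), "5 samples")
  d <- rode_dataset(matrix(1:6, 6, 1), c(0, 1, 2, 4, 5, 6))
  expect_error(compute_derivatives(d, derivative_policy("finite_difference")),
               "uniformly")
})

test_that("edge truncation keeps floor-based counts per trajectory", {
  d <- rode_dataset(matrix(seq_len(50), 50, 1), seq_len(50))
  kept <- truncate_edges(d, 0.3, 0.3)
  expect_equal(nrow(kept$X), 20L)                    # 50 - 15 - 15
  expect_identical(truncate_edges(d, 0, 0)$X, d$X)   # identity at 0/0

  # multi-trajectory bookkeeping: counts reduced per trajectory, order kept
  d2 <- rode_dataset(matrix(seq_len(80), 80, 1), c(seq_len(50), seq_len(30)),
                     trajectory = rep(1:2, c(50, 30)))
  k2 <- truncate_edges(d2, 0.3, 0.3)
  expect_equal(as.vector(table(k2$trajectory)), c(20L, 12L))
  expect_false(is.unsorted(match(k2$X[, 1], d2$X[, 1])))
})

test_that("policy fractions are validated", {
  expect_error(derivative_policy("tvregdiff", truncate_head_frac = 0.6))
  expect_error(derivative_policy("tvregdiff", truncate_tail_frac = -0.1))
})
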