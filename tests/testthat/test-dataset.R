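test_that("dataset construction enforces its invariants", {
  X <- matrix(rnorm(20), 10, 2)
  d <- rode_dataset(X, 1:10)
  expect_equal(d$states, c("x1", "x2"))
  expect_equal(dim(d), c(10L, 2L))
  expect_error(rode_dataset(X, 1:9), "nrow")
  expect_error(rode_dataset(X, c(1:5, 5:9)), "strictly increasing")
  expect_error(rode_dataset(X, 1:10, Xdot = matrix(0, 9, 2)), "same shape")
  # decreasing time is fine across trajectory boundaries
  d2 <- rode_dataset(X, c(1:5, 1:5), trajectory = rep(1:2, each = 5))
  expect_equal(length(unique(d2$trajectory)), 2L)
})

test_that("datasets round-trip through CSV with derivatives and trajectories", {
  d <- simulate_benchmark(benchmark_spec("competence", n_trajectories = 3L))
  f <- tempfile(fileext = ".csv")
  write_dataset(d, f)
  back <- read_dataset(f)
  expect_equal(back$X, d$X, tolerance = 1e-12)
  expect_equal(back$Xdot, d$Xdot, tolerance = 1e-12)
  expect_identical(back$trajectory, d$trajectory)
  expect_equal(back$t, d$t)
  unlink(f)
})
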