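test_that("library sizes match the benchmark combinatorics", {
  d <- simulate_benchmark(benchmark_spec("mm"))
  expect_equal(ncol(observational_library(d, "x", 4)$B), 10L)

  dc <- simulate_benchmark(benchmark_spec("competence", n_trajectories = 2L))
  expect_equal(ncol(observational_library(dc, "x1", 6)$B), 56L)

  # penicillin: degree 3 over (x1, x2, x4) gives 20 monomials, 40 columns
  expect_equal(2L * length(polynomial_terms(3, 3)), 40L)
  # glycolysis: degree 6 over 7 states
  expect_equal(2L * length(polynomial_terms(7, 6)), 3432L)
})

test_that("the derivative block is the monomial block times dx, column-wise", {
  d <- simulate_benchmark(benchmark_spec("mm"))
  lib <- observational_library(d, "x", 4)
  m <- ncol(lib$B) %/% 2L
  for (j in seq_len(m)) {
    expect_equal(lib$B[, m + j], lib$B[, j] * d$Xdot[, "x"])
  }
})

test_that("recombining a library row with the truth reproduces the identity", {
  d <- simulate_benchmark(benchmark_spec("mm"))
  lib <- observational_library(d, "x", 4)
  tr <- implicit_truth("mm", "x")
  expect_lt(max(abs(lib$B %*% tr$xi)), 1e-12)
})

test_that("missing derivatives are refused", {
  d <- simulate_benchmark(benchmark_spec("mm"))
  d$Xdot <- NULL
  expect_error(observational_library(d, "x", 4), "derivatives")
})

test_that("libraries export to CSV with labelled columns", {
  d <- simulate_benchmark(benchmark_spec("mm"))
  lib <- observational_library(d, "x", 2)
  f <- tempfile(fileext = ".csv")
  write_library(lib, f)
  back <- utils::read.csv(f, check.names = FALSE)
  expect_equal(names(back), term_labels(lib$terms))
  expect_equal(as.matrix(back), lib$B, ignore_attr = TRUE)
  unlink(f)
})
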