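test_that("splitting the true null vector reproduces the rate law pointwise", {
  tr <- implicit_truth("mm", "x")
  rm <- split_rational(tr$xi, tr$terms)
  xg <- matrix(seq(0.01, 3, length.out = 100), ncol = 1,
               dimnames = list(NULL, "x"))
  expect_equal(predict(rm, xg), unname(benchmark_rhs("mm", xg)[, 1]),
               tolerance = 1e-12)
})

test_that("truth -> split -> evaluate matches the right-hand side on all benchmarks", {
  set.seed(31)
  for (mid in c("mm", "competence", "penicillin", "glycolysis")) {
    def_states <- switch(mid, mm = 1L, competence = 2L, penicillin = 3L, glycolysis = 7L)
    spec <- benchmark_spec(mid)
    X <- matrix(runif(50 * def_states, 0.05, 1.5), 50, def_states)
    colnames(X) <- spec$library_states
    truth_rhs <- benchmark_rhs(mid, X)
    for (s in spec$identified_states) {
      tr <- implicit_truth(mid, s)
      rm <- split_rational(tr$xi, tr$terms)
      expect_equal(predict(rm, X), unname(truth_rhs[, s]), tolerance = 1e-10)
    }
  }
})

test_that("a relation without derivative-paired support is rejected", {
  tt <- polynomial_terms("x", 2, deriv_state = "x")
  xi <- c(1, -1, 0, 0, 0, 0) / sqrt(2)   # polynomial-only relation
  expect_error(split_rational(xi, tt), "derivative-paired")
})

test_that("named parameters are recovered from clean benchmark fits", {
  bm <- bench_run("mm")
  expect_equal(unname(bm$params), c(0.6, 1.5, 0.3), tolerance = 1e-12)

  bc <- bench_run("competence")
  expect_equal(bc$params[["a1"]], 0.004, tolerance = 1e-10)
  expect_equal(bc$params[["a3"]], 0.04, tolerance = 1e-10)
  expect_equal(bc$params[["b2"]], 1854.5, tolerance = 1e-9)
})

test_that("support mismatches produce a structured error", {
  tr <- implicit_truth("mm", "x")
  xi <- tr$xi
  xi[3] <- 0.05                      # spurious x^2 term
  rm <- split_rational(xi / sqrt(sum(xi^2)), tr$terms)
  expect_error(recover_parameters(rm, "mm"), "spurious \\{x\\^2\\}")
})

test_that("identified models re-integrate to the true trajectory", {
  bm <- bench_run("mm")
  times <- seq(0, 20, 0.5)
  sim_id <- simulate(bm$fits$x, x0 = 2, times = times)
  spec <- benchmark_spec("mm", x0 = matrix(2), t_span = c(0, 20), dt = 0.5)
  sim_true <- simulate_benchmark(spec)
  expect_lt(max(abs(sim_id$X - sim_true$X)), 1e-8)
})

test_that("degenerate identified models behave as documented", {
  tt <- polynomial_terms("x", 1, deriv_state = "x")
  # zero numerator: dx/dt = 0, a constant trajectory
  rm <- split_rational(c(0, 0, 1, 0), tt)
  sim <- simulate_identified(rm, x0 = 1.5, times = 0:10)
  expect_equal(unname(sim$X[, 1]), rep(1.5, 11), tolerance = 1e-12)
  # denominator crossing zero along the trajectory is reported with a time
  rm2 <- split_rational(c(1, 0, -0.5, 1), tt)    # dx/dt = -1/(x - 0.5)
  expect_error(simulate_identified(rm2, x0 = 1, times = seq(0, 2, 0.1)),
               "crosses zero near t =")
})
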