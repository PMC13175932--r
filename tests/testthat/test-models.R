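test_that("Michaelis-Menten right-hand side has the printed behaviour", {
  # at x = 0 the rational uptake term vanishes, leaving the input rate
  expect_equal(benchmark_rhs("mm", 0), c(x = 0.6))
  # the equilibrium solves jx = Vmax x/(Km + x) analytically at x = 0.2
  expect_equal(unname(benchmark_rhs("mm", 0.2)), 0, tolerance = 1e-15)
})

test_that("glycolysis right-hand side matches a hand-coded term-by-term oracle", {
  oracle <- function(x) {
    x1 <- x[1]; x2 <- x[2]; x3 <- x[3]; x4 <- x[4]; x5 <- x[5]; x6 <- x[6]; x7 <- x[7]
    den <- 1 + 13.6769 * x6^4
    c(2.5 - 100 * x1 * x6 / den,
      200 * x1 * x6 / den - 6 * x2 - 6 * x2 * x7,
      6 * x2 - 64 * x3 - 6 * x2 * x7 + 16 * x3 * x6,
      64 * x3 - 13 * x4 + 13 * x5 - 16 * x3 * x6 - 100 * x4 * x7,
      1.3 * x4 - 3.1 * x5,
      -200 * x1 * x6 / den + 128 * x3 - 1.28 * x6 - 32 * x3 * x6,
      6 * x2 - 18 * x2 * x7 - 100 * x4 * x7)
  }
  set.seed(5)
  for (i in 1:10) {
    x <- runif(7, 0.05, 2.5)
    expect_equal(unname(benchmark_rhs("glycolysis", x)), oracle(x), tolerance = 1e-14)
  }
})

test_that("simulation stacks the expected number of rows and is reproducible", {
  d <- simulate_benchmark(benchmark_spec("mm"))
  expect_equal(nrow(d$X), 42L)          # 21 samples x 2 trajectories
  expect_equal(length(unique(d$trajectory)), 2L)

  spec <- benchmark_spec("competence")
  expect_equal(spec$n_trajectories, 20L)
  d1 <- simulate_benchmark(spec, seed = 3)
  d2 <- simulate_benchmark(spec, seed = 3)
  expect_identical(d1$X, d2$X)
})

test_that("exact-RHS derivatives satisfy the model at every sampled row", {
  d <- simulate_benchmark(benchmark_spec("mm"))
  expect_equal(d$Xdot, benchmark_rhs("mm", d$X), tolerance = 1e-15)
})

test_that("implicit truths have the expected support sizes", {
  expect_length(implicit_truth("mm", "x")$support, 4L)
  expect_length(implicit_truth("competence", "x1")$support, 12L)
  expect_length(implicit_truth("competence", "x2")$support, 10L)
  expect_length(implicit_truth("penicillin", "x1")$support, 7L)
  gly <- vapply(paste0("x", 1:7), function(s)
    length(implicit_truth("glycolysis", s)$support), integer(1))
  expect_equal(unname(gly), c(5L, 7L, 5L, 6L, 3L, 9L, 4L))
})

test_that("the implicit identity holds pointwise on every benchmark", {
  for (mid in c("mm", "competence", "penicillin", "glycolysis")) {
    cfg <- if (mid == "glycolysis") list(n_trajectories = 3L) else list()
    spec <- do.call(benchmark_spec, c(list(mid), cfg))
    d <- simulate_benchmark(spec, seed = 2)
    for (s in spec$identified_states) {
      tr <- implicit_truth(mid, s, params = spec$params)
      lib <- observational_library(d, s, spec$degree, spec$library_states)
      contrib <- abs(lib$B) %*% abs(tr$xi)     # scale of the largest term
      resid <- abs(lib$B %*% tr$xi)
      expect_lt(max(resid / pmax(contrib, 1e-300)), 1e-10)
    }
  }
})

test_that("add_noise follows its contract", {
  d <- simulate_benchmark(benchmark_spec("mm"))
  expect_identical(add_noise(d, 0)$X, d$X)               # bitwise at sigma 0
  expect_null(add_noise(d, 0.1)$Xdot)                    # derivatives dropped
  expect_identical(add_noise(d, 0.1, seed = 9)$X, add_noise(d, 0.1, seed = 9)$X)
  expect_error(add_noise(d, -1), "non-negative")

  big <- rode_dataset(matrix(0, 2e4, 1), seq_len(2e4))
  nz <- add_noise(big, 0.1, seed = 1)
  expect_equal(stats::sd(nz$X - big$X), 0.1, tolerance = 0.05)
})

test_that("benchmark spec round-trips through YAML and JSON", {
  spec <- benchmark_spec("competence", n_trajectories = 5L)
  for (ext in c("yaml", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_benchmark_spec(spec, f)
    back <- read_benchmark_spec(f)
    expect_equal(back$params, spec$params)
    expect_equal(back$n_trajectories, spec$n_trajectories)
    expect_equal(back$t_span, spec$t_span)
    unlink(f)
  }
})

test_that("unsupported penicillin operating modes are rejected", {
  p <- benchmark_params("penicillin")
  p["F"] <- 0.1
  expect_error(benchmark_rhs("penicillin", c(0, 5, 0.1), p), "batch")
})
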