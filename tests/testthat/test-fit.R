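test_that("planted rational systems are recovered exactly from exact derivatives", {
  # randomised property: scattered states, dx = N(x)/D(x) planted by hand
  for (seed in 1:8) {
    ps <- planted_system(seed, n_states = 1L, degree = 4L)
    # the clean-data near-null cluster is degenerate by construction, so the
    # Gram route warns and applies the minimal-degree rule
    fit <- suppressWarnings(rational_ode(ps$data, "x1", 4, selection = "gram"))
    expect_equal(fit$support, ps$support)
    expect_lt(parameter_error(ps$xi, fit$nullvector$xi), 1e-10)
  }
  for (seed in 1:4) {
    ps <- planted_system(100 + seed, n_states = 2L, degree = 3L, p = 400L)
    fit <- suppressWarnings(rational_ode(ps$data, "x1", 3, selection = "gram"))
    expect_equal(fit$support, ps$support)
    expect_lt(parameter_error(ps$xi, fit$nullvector$xi), 1e-10)
  }
})

test_that("the scan and the Gram pipeline agree on the clean one-state benchmark", {
  d <- simulate_benchmark(benchmark_spec("mm"))
  f1 <- rational_ode(d, "x", 4, selection = "scan")
  f2 <- suppressWarnings(rational_ode(d, "x", 4, selection = "gram"))
  # (the Gram route warns about the degenerate clean-data cluster)
  expect_equal(f1$support, f2$support)
  expect_lt(parameter_error(f1$nullvector$xi, f2$nullvector$xi), 1e-9)
})

test_that("identification is invariant to the scale of the data rows", {
  ps <- planted_system(11)
  f1 <- rational_ode(ps$data, "x1", 4)
  d2 <- ps$data
  # common positive row scaling of the library corresponds to scaling B
  lib <- observational_library(ps$data, "x1", 4)
  nv1 <- suppressWarnings(null_vector(gram(lib$B), lib$terms))
  nv2 <- suppressWarnings(null_vector(gram(7 * lib$B), lib$terms))
  expect_lt(max(abs(nv1$xi - nv2$xi)), 1e-6)
  # and the reported vector has its largest entry positive (sign convention)
  expect_gt(f1$nullvector$xi[which.max(abs(f1$nullvector$xi))], 0)
})

test_that("the fit object supports the standard modelling verbs", {
  d <- simulate_benchmark(benchmark_spec("mm"))
  fit <- rational_ode(d, "x", 4)
  expect_s3_class(fit, "rational_ode")
  expect_output(print(fit), "d x/dt|dx/dt")
  expect_named(coef(fit), term_labels(fit$terms))
  expect_equal(length(coef(fit, "model")$numerator), 5L)
  expect_equal(predict(fit), benchmark_rhs("mm", d$X)[, 1], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(max(abs(residuals(fit))), 1e-10)
  expect_lt(max(abs(residuals(fit, "derivative"))), 1e-9)
  s <- summary(fit)
  expect_s3_class(s, "summary.rational_ode")
  expect_output(print(s), "active terms")
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f)); unlink(f)
})

test_that("fits refuse datasets without derivatives", {
  d <- simulate_benchmark(benchmark_spec("mm"))
  d$Xdot <- NULL
  expect_error(rational_ode(d, "x", 4), "derivatives")
})
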