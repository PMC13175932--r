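test_that("the clean one-state benchmark identifies its exact structure", {
  bm <- bench_run("mm")
  expect_equal(bm$report$structural_error, 0)
  expect_equal(bm$report$per_state$support_size, 4L)
})

test_that("benchmark runs are deterministic under a fixed seed", {
  a <- run_benchmark("mm", seed = 5)
  b <- run_benchmark("mm", seed = 5)
  expect_identical(a$params, b$params)
  expect_identical(a$report$per_state, b$report$per_state)
})

test_that("noise sweep configuration validates its invariants", {
  expect_error(noise_sweep_config(sigma_levels = c(0.1, 0.01)))  # unsorted
  expect_error(noise_sweep_config(sigma_levels = c(-1, 0.1)))
  expect_error(noise_sweep_config(n_initial_conditions = 0))
  cfg <- noise_sweep_config()
  expect_length(cfg$sigma_levels, 23L)
  expect_equal(range(cfg$sigma_levels), c(1e-7, 0.5))
  expect_equal(cfg$n_initial_conditions, 2400L)
})

test_that("a tiny-noise sweep reduces to the clean benchmark structure", {
  cfg <- noise_sweep_config(sigma_levels = 1e-7,
                            n_initial_conditions = 40L, seed = 7)
  sw <- cached("sweep_tiny", noise_sweep(cfg))
  expect_equal(sw$structural_error, 0)
  expect_equal(sw$support_size, 4L)
  # determinism contract
  sw2 <- noise_sweep(cfg)
  expect_identical(as.data.frame(sw), as.data.frame(sw2))
})

test_that("reports round-trip through JSON", {
  bm <- bench_run("mm")
  dir <- tempfile()
  paths <- write_report(bm, dir)
  rep <- jsonlite::read_json(paths[["json"]], simplifyVector = TRUE)
  expect_equal(rep$structural_error, bm$report$structural_error)
  expect_equal(rep$frobenius_error, bm$report$frobenius_error)
  expect_equal(unlist(rep$params_identified), bm$params, tolerance = 1e-12)
  expect_setequal(rep$equations$x$support,
                  term_labels(bm$fits$x$terms)[bm$fits$x$support])
  unlink(dir, recursive = TRUE)
})

test_that("empty tabular results still produce a header-only CSV", {
  dir <- tempfile()
  paths <- write_report(data.frame(sigma = numeric(0),
                                   structural_error = numeric(0)), dir)
  lines <- readLines(paths[["csv"]])
  expect_length(lines, 1L)
  expect_match(lines, "sigma")
  unlink(dir, recursive = TRUE)
})
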