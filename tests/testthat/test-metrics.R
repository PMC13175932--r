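test_that("structural error reproduces the worked examples", {
  expect_equal(structural_error(1:4, 1:3), 0.25)   # three of four, one missing
  expect_equal(structural_error(1:4, 1:5), 0.2)    # all four plus one spurious
  expect_equal(structural_error(1:4, 1:4), 0)      # perfect match
})

test_that("structural error is zero iff supports are equal and grows with mistakes", {
  set.seed(2)
  for (rep in 1:25) {
    st <- sample(50, sample(3:10, 1))
    e0 <- structural_error(st, st)
    expect_equal(e0, 0)
    extra <- setdiff(seq_len(60), st)[1]
    expect_gt(structural_error(st, c(st, extra)), 0)
    expect_gt(structural_error(st, st[-1]), 0)
    # adding a second spurious term strictly increases the score
    extra2 <- setdiff(seq_len(60), st)[2]
    expect_gt(structural_error(st, c(st, extra, extra2)),
              structural_error(st, c(st, extra)))
    # and the score always stays within [0, 1]
    rand <- sample(60, sample(1:10, 1))
    e <- structural_error(st, rand)
    expect_gte(e, 0); expect_lte(e, 1)
  }
  expect_error(structural_error(integer(0), 1:3), "non-empty")
})

test_that("parameter error matches hand-computed cases and its invariances", {
  xi <- c(0.3, -0.7, 0.648)
  expect_equal(parameter_error(xi, xi), 0)
  expect_equal(parameter_error(xi, 2 * xi), 0)       # scale invariance
  expect_equal(parameter_error(xi, -xi), 0)          # sign alignment
  expect_equal(parameter_error(c(1, 0), c(0.6, 0.8)),
               sqrt((1 - 0.6)^2 + 0.8^2))            # = 0.894427...
  expect_error(parameter_error(c(0, 0), c(1, 0)), "zero")
})

test_that("relative Frobenius error handles named alignment and signs", {
  expect_equal(relative_frobenius(c(Km = 0.3), c(Km = 0.33)), 0.1)
  tru <- c(a = 1, b = -2)
  expect_equal(relative_frobenius(tru, c(b = -2, a = 1)), 0)   # name matching
  expect_equal(relative_frobenius(tru, c(a = 1, b = 2),
                                  sign_insensitive = TRUE), 0)
  expect_error(relative_frobenius(tru, c(a = 1)), "missing")
  expect_error(relative_frobenius(c(a = 0), c(a = 1)), "zero")
})
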