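test_that("monomial counts follow the binomial formula", {
  expect_equal(length(polynomial_terms(1, 4)), 5L)           # 1, x, ..., x^4
  expect_equal(length(polynomial_terms(2, 2)), 6L)
  expect_equal(length(polynomial_terms(7, 6)), choose(13, 6)) # 1716
  for (n in 1:4) for (d in 0:4) {
    expect_equal(length(polynomial_terms(n, d)), choose(n + d, d))
  }
})

test_that("graded-lexicographic order matches the conventional layout", {
  tt <- polynomial_terms(c("x1", "x2"), 2)
  expect_equal(term_labels(tt), c("1", "x1", "x2", "x1^2", "x1*x2", "x2^2"))
  t1 <- polynomial_terms("x", 4)
  expect_equal(term_labels(t1), c("1", "x", "x^2", "x^3", "x^4"))
})

test_that("term ordering is a deterministic pure function of its inputs", {
  a <- polynomial_terms(3, 5)
  b <- polynomial_terms(3, 5)
  expect_identical(a$exponents, b$exponents)
})

test_that("derivative pairing doubles the term set in matching order", {
  tt <- polynomial_terms(c("u", "v"), 3, deriv_state = "u")
  m <- length(tt) %/% 2L
  expect_equal(length(tt), 2L * choose(5, 3))
  expect_identical(tt$exponents[seq_len(m), ], tt$exponents[m + seq_len(m), ])
  expect_identical(tt$with_deriv, rep(c(FALSE, TRUE), each = m))
  lab <- term_labels(tt)
  expect_equal(lab[m + 1L], "du")
  expect_equal(lab[m + 2L], "u*du")
})
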