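test_that("the Gram matrix of orthonormal columns is the identity", {
  Q <- qr.Q(qr(matrix(rnorm(200 * 6), 200, 6)))
  expect_equal(gram(Q), diag(6), tolerance = 1e-12)
})

test_that("Gram eigenvectors agree with the right singular vectors of B", {
  set.seed(42)
  for (rep in 1:10) {
    B <- matrix(rnorm(50 * 6), 50, 6)
    V_svd <- svd(B)$v
    V_eig <- eigen(gram(B), symmetric = TRUE)$vectors
    for (j in 1:6) {
      expect_gt(abs(sum(V_svd[, j] * V_eig[, j])), 1 - 1e-10)
    }
  }
})

test_that("oracle equivalence: null_vector(gram(B)) matches the last right singular vector", {
  set.seed(7)
  for (rep in 1:20) {
    q <- sample(3:12, 1)
    B <- matrix(rnorm(40 * q), 40, q)
    s <- svd(B)
    if (s$d[q - 1L] - s$d[q] < 1e-6) next   # only for separated smallest sigma
    v <- s$v[, q]
    if (v[which.max(abs(v))] < 0) v <- -v
    nv <- null_vector(gram(B))
    expect_lt(sqrt(sum((nv$xi - v)^2)), 1e-8)
  }
})

test_that("the Gram reduction keeps its q x q shape for tall data", {
  B <- matrix(rnorm(1e5), ncol = 10)
  expect_equal(dim(gram(B)), c(10L, 10L))
})

test_that("a planted two-column dependence is recovered up to the sign rule", {
  set.seed(1)
  c1 <- rnorm(30)
  G <- gram(cbind(c1, 2 * c1))
  nv <- null_vector(G)
  target <- c(2, -1) / sqrt(5)   # hand-solved 2x2 eigenproblem
  if (target[which.max(abs(target))] < 0) target <- -target
  expect_equal(abs(nv$xi), abs(target), tolerance = 1e-10)
  expect_gt(nv$xi[which.max(abs(nv$xi))], 0)
})

test_that("sparsify zeroes sub-threshold entries and renormalises", {
  xi <- c(1, 1e-9, 0.5)
  nv <- structure(list(xi = xi / sqrt(sum(xi^2)), singular_values = c(1, 1, 0),
                       chosen_index = 3L, cluster_dim = 1L,
                       support = 1:3, lambda = NA_real_, terms = NULL),
                  class = "rode_nullvector")
  sp <- sparsify(nv)
  expect_equal(sp$support, c(1L, 3L))
  expect_equal(sum(sp$xi^2), 1)

  nv$xi <- c(0.6, 0.64, 0.48)   # all entries far above the threshold
  expect_equal(sparsify(nv)$support, 1:3)
  nv$xi <- c(1e-9, 1e-10, 1e-8)
  expect_error(sparsify(nv), "degenerate")
})

test_that("the null vector is invariant to a common row scaling", {
  set.seed(3)
  c1 <- rnorm(30)
  B <- cbind(c1, rnorm(30), 3 * c1)
  expect_equal(null_vector(gram(B))$xi, null_vector(gram(5.5 * B))$xi,
               tolerance = 1e-9)
})

test_that("a degenerate near-null cluster triggers a warning and the minimal-degree rule", {
  d <- simulate_benchmark(benchmark_spec("mm"))
  lib <- observational_library(d, "x", 4)
  expect_warning(nv <- null_vector(gram(lib), lib$terms), "cluster")
  sp <- sparsify(nv)
  expect_equal(sp$support, c(1L, 2L, 6L, 7L))   # 1, x, dx, x*dx
  expect_gt(nv$cluster_dim, 1L)
})

test_that("non-symmetric observables are rejected", {
  M <- matrix(rnorm(16), 4, 4)
  expect_error(null_vector(M), "symmetric")
})
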