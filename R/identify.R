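#' Observable (Gram) matrix of a library
#'
#' Condenses a p x q observational library into the q x q matrix `B'B`.  The
#' eigenvectors of the Gram matrix are the right singular vectors of `B`, so
#' the null-space extraction can work on a matrix whose size is independent
#' of the number of samples — the key to handling long recordings cheaply.
#'
#' @param B A numeric matrix or a `"rode_library"`.
#' @return Symmetric q x q matrix.
#' @export
gram <- function(B) {
  if (inherits(B, "rode_library")) B <- B$B
  if (!is.matrix(B) || nrow(B) == 0L) stop("B must be a non-empty matrix")
  crossprod(B)
}

#' Extract the null vector of an observable matrix
#'
#' Computes the eigendecomposition of the symmetric observable matrix and
#' returns the unit-norm eigenvector of the smallest eigenvalue — the right
#' singular vector of the library for the singular value closest to zero,
#' whose entries are the implicit-model coefficients.  Eigenvalues are
#' reported as singular values (their clipped square roots).
#'
#' On noise-free data the null space is usually multi-dimensional: every
#' polynomial multiple of the true implicit relation that still fits inside
#' the library is also a null vector.  When several singular values fall
#' below `null_tol` times the largest, the default `"minimal_degree"` policy
#' therefore peels the near-null cluster from the highest monomial degree
#' downwards, keeping at each level the subspace with vanishing coefficients
#' on that degree, until a single direction — the minimal-degree relation —
#' remains.  `degenerate = "smallest"` skips the refinement and returns the
#' raw smallest-eigenvalue vector (with a warning when the cluster is
#' degenerate).
#'
#' The sign is fixed so that the largest-magnitude entry is positive.
#'
#' @param G Symmetric observable matrix (or a `"rode_library"`, whose Gram
#'   matrix is then taken).
#' @param terms Optional `"rode_terms"` (required for `"minimal_degree"`).
#' @param null_tol Relative singular-value threshold defining the near-null
#'   cluster.  The default 1e-6 sits above the sqrt(machine eps) noise floor
#'   of Gram eigenvalues.
#' @param degenerate Cluster policy: `"minimal_degree"` or `"smallest"`.
#' @return An object of class `"rode_nullvector"`: list with `xi`,
#'   `singular_values` (descending), `chosen_index`, `cluster_dim`,
#'   `support`, `lambda` (NA until sparsified) and `terms`.
#' @export
null_vector <- function(G, terms = NULL, null_tol = 1e-6,
                        degenerate = c("minimal_degree", "smallest")) {
  degenerate <- match.arg(degenerate)
  if (inherits(G, "rode_library")) {
    terms <- terms %||% G$terms
    G <- gram(G)
  }
  q <- ncol(G)
  if (max(abs(G - t(G))) > 1e-8 * max(abs(G), 1e-300)) {
    stop("observable matrix is not symmetric")
  }
  eig <- eigen((G + t(G)) / 2, symmetric = TRUE)
  sigma <- sqrt(pmax(eig$values, 0))          # descending
  smax <- sigma[1L]
  asc <- rev(seq_len(q))
  V <- eig$vectors[, asc, drop = FALSE]       # ascending eigenvalue order
  sig_asc <- sigma[asc]
  r <- max(1L, sum(sig_asc < null_tol * smax))
  if (r > 1L && sig_asc[2L] - sig_asc[1L] < 1e-12 * smax && degenerate == "smallest") {
    warning(sprintf("smallest singular value is repeated within tolerance; %d-dimensional near-null cluster, returning the lowest-index vector", r))
  }
  xi <- V[, 1L]
  cluster_dim <- r
  if (r > 1L) {
    if (degenerate == "minimal_degree" && !is.null(terms)) {
      warning(sprintf("near-null cluster of dimension %d (relative singular values %s); selecting the minimal-degree element", r,
                      paste(signif(sig_asc[seq_len(min(r, 4L))] / smax, 2), collapse = ", ")))
      xi <- .peel_minimal_degree(V[, seq_len(r), drop = FALSE], .term_degrees(terms))
    } else if (degenerate == "minimal_degree") {
      warning("near-null cluster is degenerate but no term set was supplied; returning the smallest-eigenvalue vector")
    }
  }
  xi <- xi / sqrt(sum(xi^2))
  if (xi[which.max(abs(xi))] < 0) xi <- -xi
  structure(list(xi = xi, singular_values = sigma, chosen_index = q,
                 cluster_dim = cluster_dim, support = which(xi != 0),
                 lambda = NA_real_, terms = terms),
            class = "rode_nullvector")
}

# Select the minimal-degree element of a null-space basis: walk the monomial
# degrees from the top down and restrict to the sub-basis with (numerically)
# zero coefficients at that degree, splitting zero from non-zero singular
# values at their largest logarithmic gap.  Exact when the cluster is the
# span of polynomial multiples of one coprime relation.
.peel_minimal_degree <- function(Vc, deg_col) {
  for (d in sort(unique(deg_col), decreasing = TRUE)) {
    if (ncol(Vc) == 1L) break
    M <- Vc[deg_col == d, , drop = FALSE]
    sv <- svd(M, nu = 0, nv = ncol(Vc))
    dvals <- c(sv$d, rep(0, ncol(Vc) - length(sv$d)))
    keep <- dvals < 1e-6
    if (!any(keep) && any(dvals > 0)) {
      # gap-based split for noisy clusters
      pos <- sort(dvals[dvals > 1e-300])
      if (length(pos) >= 2L) {
        gaps <- diff(log(pos))
        cut <- which.max(gaps)
        if (gaps[cut] > log(100)) keep <- dvals <= pos[cut]
      }
    }
    if (!any(keep) || all(keep)) next
    Vc <- Vc %*% sv$v[, keep, drop = FALSE]
    Vc <- qr.Q(qr(Vc))
  }
  Vc[, 1L]
}

#' Sparsify a null vector with a fixed threshold
#'
#' Entries of the unit-norm coefficient vector whose magnitude is below
#' `lambda` are set to exactly zero and the remainder re-normalised to unit
#' norm.  The threshold's role is to remove near-zero coefficients produced
#' by numerical round-off, not to act as a tuned sparsity penalty; 1e-7 is
#' kept fixed across problems.
#'
#' @param nv A `"rode_nullvector"`.
#' @param lambda Threshold (default 1e-7).
#' @return The sparsified `"rode_nullvector"` with its `support` updated.
#' @export
sparsify <- function(nv, lambda = 1e-7) {
  stopifnot(inherits(nv, "rode_nullvector"), lambda >= 0)
  xi <- nv$xi
  xi[abs(xi) < lambda] <- 0
  if (all(xi == 0)) {
    stop("every coefficient fell below the threshold; degenerate model")
  }
  xi <- xi / sqrt(sum(xi^2))
  nv$xi <- xi
  nv$support <- which(xi != 0)
  nv$lambda <- lambda
  nv
}

#' @export
print.rode_nullvector <- function(x, ...) {
  q <- length(x$xi)
  cat(sprintf("Null vector over %d library terms; support %d%s; smallest/largest singular value %.3g / %.3g\n",
              q, length(x$support),
              if (is.na(x$lambda)) "" else sprintf(" (lambda = %g)", x$lambda),
              min(x$singular_values), max(x$singular_values)))
  if (!is.null(x$terms) && length(x$support) <= 30L) {
    lab <- term_labels(x$terms)
    cat(" ", paste(sprintf("%s: %.6g", lab[x$support], x$xi[x$support]),
                   collapse = "  "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.rode_nullvector <- function(x, ...) {
  data.frame(term = if (is.null(x$terms)) seq_along(x$xi) else term_labels(x$terms),
             coefficient = x$xi,
             singular_value = rev(x$singular_values)[seq_along(x$xi)])
}

## ---- internal fitting primitives shared by the front ends ----

# smallest right singular vector of B (column-scaled for conditioning),
# followed by the threshold/refit fixed point:
#   threshold at lambda -> re-estimate on the surviving columns (smallest
#   right singular vector of the restricted matrix) -> re-threshold ...
# Returns NULL when everything is eliminated.
.fit_restricted <- function(B, lambda = 1e-7, max_iter = 10L) {
  q <- ncol(B)
  cs <- sqrt(colSums(B^2))
  if (any(cs == 0)) return(NULL)
  sv <- svd(sweep(B, 2L, cs, "/"), nu = 0, nv = q)
  xi <- sv$v[, q] / cs
  xi <- xi / sqrt(sum(xi^2))
  res <- .refit_loop(B, xi, lambda, max_iter)
  if (is.null(res)) return(NULL)
  res$sigma_ratio <- sv$d[q] / sv$d[1L]
  res
}

.refit_loop <- function(B, xi, lambda = 1e-7, max_iter = 10L) {
  q <- ncol(B)
  for (it in seq_len(max_iter)) {
    supp <- which(abs(xi) >= lambda)
    if (!length(supp)) return(NULL)
    Bs <- B[, supp, drop = FALSE]
    cs <- sqrt(colSums(Bs^2))     # keep the column scaling of the first pass
    sv <- svd(Bs / rep(cs, each = nrow(Bs)), nu = 0)
    v <- sv$v[, length(supp)] / cs
    v <- v / sqrt(sum(v^2))
    xin <- numeric(q)
    xin[supp] <- v
    xin <- xin / sqrt(sum(xin^2))
    snew <- which(abs(xin) >= lambda)
    if (!length(snew)) return(NULL)
    converged <- identical(snew, supp)
    xi <- numeric(q)
    xi[snew] <- xin[snew]
    xi <- xi / sqrt(sum(xi^2))
    if (converged) break
  }
  if (xi[which.max(abs(xi))] < 0) xi <- -xi
  list(xi = xi, support = which(xi != 0))
}

# relative error with which the implicit relation reconstructs the stored
# derivative: dx_hat = -(Theta a)/(Theta b), compared to dx.  The 90th
# percentile of the absolute deviation is used: robust to the few rows where
# the denominator polynomial is small, yet still sensitive to a relation
# that only fits a majority of the data (a median would let a sub-library
# pass whenever the terms it lacks are negligible on half the rows).
.reconstruction_error <- function(xi, lib, rows = NULL) {
  m <- length(xi) %/% 2L
  if (is.null(rows)) rows <- rep(TRUE, nrow(lib$B))
  a <- xi[seq_len(m)]
  b <- xi[m + seq_len(m)]
  if (max(abs(b)) == 0) return(Inf)
  # only touch the columns that carry coefficients (B can be very wide)
  nza <- which(a != 0)
  nzb <- which(b != 0)
  xd <- lib$B[rows, m + 1L]         # constant * dx column is dx itself
  num <- if (length(nza))
    drop(lib$B[rows, nza, drop = FALSE] %*% a[nza]) else numeric(sum(rows))
  den <- drop(lib$B[rows, nzb, drop = FALSE] %*% b[nzb])
  ok <- abs(den) > 1e-8 * stats::median(abs(den))
  if (mean(ok) < 0.8) return(Inf)
  pred <- -num[ok] / den[ok]
  scale <- stats::median(abs(xd[ok]))
  if (scale == 0) return(Inf)
  stats::quantile(abs(pred - xd[ok]), 0.9, names = FALSE) / scale
}
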