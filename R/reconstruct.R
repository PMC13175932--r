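#' Split a null vector into an explicit rational model
#'
#' Rearranges the implicit relation `Theta(x) a + dx_k Theta(x) b = 0` into
#' the explicit rational equation `dx_k = -(Theta a) / (Theta b)`: the
#' numerator coefficients are `-a`, the denominator coefficients are `b`.
#' Both are rescaled so that the denominator's largest-magnitude coefficient
#' (the pivot) equals one, a deterministic and scale-free normalisation.
#'
#' @param nv A `"rode_nullvector"` (typically sparsified) or a bare numeric
#'   vector of length `2 m`.
#' @param terms The library term set (taken from `nv` when present).
#' @return An object of class `"rational_model"`: list with `state`,
#'   `monomials` (a derivative-free `"rode_terms"`), `numer`, `denom`,
#'   `pivot` (index of the pivot monomial).
#' @export
split_rational <- function(nv, terms = NULL) {
  if (inherits(nv, "rode_nullvector")) {
    terms <- terms %||% nv$terms
    xi <- nv$xi
  } else {
    xi <- as.numeric(nv)
  }
  if (is.null(terms)) stop("a term set is required")
  m <- length(xi) %/% 2L
  stopifnot(length(xi) == 2L * m, length(terms) == 2L * m)
  a <- xi[seq_len(m)]
  b <- xi[m + seq_len(m)]
  if (all(b == 0)) {
    stop("no derivative-paired term survives: the relation contains no ",
         "denominator and does not define an explicit rational equation")
  }
  pivot <- which.max(abs(b))
  s <- b[pivot]
  monomials <- polynomial_terms(terms$states, terms$degree)
  structure(list(state = terms$deriv_state, monomials = monomials,
                 numer = -a / s, denom = b / s, pivot = pivot),
            class = "rational_model")
}

#' @export
format.rational_model <- function(x, digits = 6, ...) {
  lab <- term_labels(x$monomials)
  fmt <- function(coefs) {
    nz <- which(coefs != 0)
    if (!length(nz)) return("0")
    pieces <- sprintf("%s%s", signif(coefs[nz], digits),
                      ifelse(lab[nz] == "1", "", paste0("*", lab[nz])))
    paste(pieces, collapse = " + ")
  }
  sprintf("d%s/dt = (%s) / (%s)", x$state, fmt(x$numer), fmt(x$denom))
}

#' @export
print.rational_model <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
predict.rational_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(colnames(X)) && all(object$monomials$states %in% colnames(X))) {
    X <- X[, object$monomials$states, drop = FALSE]
  }
  Th <- .eval_monomials(X, object$monomials$exponents)
  den <- drop(Th %*% object$denom)
  if (any(den == 0)) stop("denominator vanishes at a supplied state")
  drop(Th %*% object$numer) / den
}

#' Recover named kinetic parameters from identified models
#'
#' Inverts the benchmark-specific map from implicit polynomial coefficients
#' to the named parameters of the governing equations (for instance, for
#' Michaelis-Menten kinetics the denominator `Km + x` and numerator
#' `jx Km + (jx - Vmax) x` yield `jx`, `Vmax`, `Km`).  The identified support
#' must match the benchmark's expected support; a mismatch raises an error
#' listing the missing and spurious terms.
#'
#' @param fits A single `"rational_ode"` fit (or `"rational_model"`), or a
#'   list of fits covering the benchmark's identified equations, in state
#'   order.
#' @param model_id Benchmark identifier.
#' @return Named numeric vector of recovered parameters: `(jx, Vmax, Km)`
#'   for `mm`; `(a1, a2, a3, b1, b2)` for `competence`;
#'   `(mu_p, K_p, K, K1)` for `penicillin`; the 26 term coefficients for
#'   `glycolysis`.
#' @export
recover_parameters <- function(fits, model_id) {
  model_id <- match.arg(model_id, .BENCHMARKS)
  if (inherits(fits, "rational_ode") || inherits(fits, "rational_model")) {
    fits <- list(fits)
  }
  models <- lapply(fits, function(f) {
    if (inherits(f, "rational_ode")) f$model else f
  })
  def <- .model_def(model_id)
  for (i in seq_along(models)) {
    .check_support(models[[i]], def, model_id)
  }
  cf <- function(i, what, label) {
    mdl <- models[[i]]
    idx <- match(label, term_labels(mdl$monomials))
    if (is.na(idx)) stop("term '", label, "' not in the model's monomial set")
    mdl[[what]][idx]
  }
  switch(model_id,
    mm = {
      n0 <- cf(1, "numer", "1"); n1 <- cf(1, "numer", "x")
      d0 <- cf(1, "denom", "1"); d1 <- cf(1, "denom", "x")
      Km <- d0 / d1
      jx <- n0 / d0
      Vmax <- jx - n1 / d1
      c(jx = jx, Vmax = Vmax, Km = Km)
    },
    competence = {
      if (length(models) < 2L) stop("competence needs the x1 and x2 fits")
      s <- cf(1, "denom", "x1^2")
      a3 <- cf(1, "denom", "1") / s
      a1 <- cf(1, "numer", "1") / (a3 * s)
      a2 <- cf(1, "numer", "x1^2") / s - a1
      s2 <- cf(2, "denom", "1")
      b2 <- cf(2, "denom", "x1^5") / s2
      b1 <- cf(2, "numer", "1") / s2
      c(a1 = a1, a2 = a2, a3 = a3, b1 = b1, b2 = b2)
    },
    penicillin = {
      d0 <- cf(1, "denom", "1"); d1 <- cf(1, "denom", "x2"); d2 <- cf(1, "denom", "x2^2")
      # D = s (K_p + (1 + K_p/K1) x2 + x2^2/K1): s solves s^2 - d1 s + d0 d2 = 0
      disc <- d1^2 - 4 * d0 * d2
      if (disc < 0) stop("denominator coefficients are inconsistent with substrate-inhibition kinetics")
      s <- (d1 + sqrt(disc)) / 2
      c(mu_p = cf(1, "numer", "x2*x4") / s,
        K_p = d0 / s,
        K = -cf(1, "numer", "x1") / d0,
        K1 = s / d2)
    },
    glycolysis = {
      if (length(models) < 7L) stop("glycolysis needs fits for all seven equations")
      den_ratio <- function(i) cf(i, "denom", "x6^4") / cf(i, "denom", "1")
      nm <- function(i, label) cf(i, "numer", label) / cf(i, "denom", "1")
      c(c1 = nm(1, "1"), c2 = nm(1, "x1*x6"), c3 = den_ratio(1),
        d1 = nm(2, "x1*x6"), d2 = den_ratio(2), d3 = nm(2, "x2"), d4 = nm(2, "x2*x7"),
        e1 = nm(3, "x2"), e2 = nm(3, "x3"), e3 = nm(3, "x2*x7"), e4 = nm(3, "x3*x6"),
        f1 = nm(4, "x3"), f2 = nm(4, "x4"), f3 = nm(4, "x5"),
        f4 = nm(4, "x3*x6"), f5 = nm(4, "x4*x7"),
        g1 = nm(5, "x4"), g2 = nm(5, "x5"),
        h1 = nm(6, "x1*x6"), h2 = den_ratio(6), h3 = nm(6, "x3"),
        h4 = nm(6, "x3*x6"), h5 = nm(6, "x6"),
        j1 = nm(7, "x2"), j2 = nm(7, "x2*x7"), j3 = nm(7, "x4*x7"))
    })
}

# structured support check: compare an identified model's nonzero terms to
# the benchmark truth for its equation
.check_support <- function(model, def, model_id) {
  st <- model$state
  if (is.null(st) || !st %in% def$identified) {
    stop("model state '", st, "' is not an identified equation of '", model_id, "'")
  }
  ND <- def$ND[[st]]
  lab <- term_labels(model$monomials)
  key <- function(p) apply(p$E, 1L, paste, collapse = ",")
  keym <- apply(model$monomials$exponents, 1L, paste, collapse = ",")
  want_n <- lab[match(key(ND$N), keym)]
  want_d <- lab[match(key(ND$D), keym)]
  got_n <- lab[model$numer != 0]
  got_d <- lab[model$denom != 0]
  missing <- c(setdiff(want_n, got_n), paste0(setdiff(want_d, got_d), "*dx"))
  spurious <- c(setdiff(got_n, want_n), paste0(setdiff(got_d, want_d), "*dx"))
  missing <- setdiff(missing, "*dx"); spurious <- setdiff(spurious, "*dx")
  if (length(missing) || length(spurious)) {
    stop(sprintf("support of the %s equation does not match '%s': missing {%s}, spurious {%s}",
                 st, model_id, paste(missing, collapse = ", "),
                 paste(spurious, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Integrate identified rational models
#'
#' Re-simulates the dynamical system defined by one or more identified
#' rational models (one per state) from an initial condition, with the same
#' stiff-capable solver and tolerance conventions as the benchmark
#' generators.  The denominator of every equation is monitored; if it
#' crosses zero along the trajectory, an error reports the crossing time.
#'
#' @param models A single `"rational_model"`/`"rational_ode"` (for a
#'   one-state system) or a list covering every state, in state order.
#' @param x0 Initial state vector.
#' @param times Output time grid.
#' @param rtol,atol Integrator tolerances.
#' @return A `"rode_dataset"` holding the simulated trajectory.
#' @export
simulate_identified <- function(models, x0, times, rtol = 1e-12, atol = 1e-12) {
  if (inherits(models, "rational_ode") || inherits(models, "rational_model")) {
    models <- list(models)
  }
  models <- lapply(models, function(f) if (inherits(f, "rational_ode")) f$model else f)
  n <- length(models)
  states <- models[[1L]]$monomials$states
  if (length(states) != n) {
    stop("need one model per state: got ", n, " models for states ",
         paste(states, collapse = ", "))
  }
  fn <- function(t, y, p) {
    X <- matrix(y, 1L)
    d <- vapply(models, function(mdl) {
      Th <- .eval_monomials(X, mdl$monomials$exponents)
      den <- drop(Th %*% mdl$denom)
      if (!is.finite(den) || abs(den) < 1e-12) {
        stop(sprintf("denominator of d%s crosses zero near t = %g",
                     mdl$state, t), call. = FALSE)
      }
      drop(Th %*% mdl$numer) / den
    }, numeric(1))
    list(d)
  }
  sol <- deSolve::ode(x0, times, fn, NULL, method = "lsoda", rtol = rtol, atol = atol)
  if (nrow(sol) < length(times)) {
    stop("integration of the identified model stopped early at t = ",
         sol[nrow(sol), 1L])
  }
  X <- unname(sol[, -1L, drop = FALSE])
  colnames(X) <- states
  rode_dataset(X, sol[, 1L])
}
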