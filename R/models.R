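## Benchmark generators: four classic biochemical systems with rational-form
## dynamics.  Each identified state equation is stored symbolically as a
## numerator/denominator polynomial pair, so the simulation right-hand side,
## the implicit ground-truth coefficient vector and the parameter-recovery
## maps all share one definition.

.BENCHMARKS <- c("mm", "competence", "penicillin", "glycolysis")

#' True parameter values of the benchmark systems
#'
#' Returns the named parameter vector used by the simulators: the
#' Michaelis-Menten uptake model (substrate input rate `jx`, maximal rate
#' `Vmax`, Michaelis constant `Km`), the two-state B. subtilis competence
#' circuit (`a1`, `a2`, `a3`, `b1`, `b2`), penicillin production kinetics
#' (`mu_p`, `K_p`, `K`, `K1`, `F`, plus the biomass/substrate drive
#' `mu_x`, `K_x`, `Y_xs`, `Y_ps`, `m_x`, `K_mx`) and the seven-state yeast
#' glycolysis oscillator (26 named term coefficients `c1..j3`).
#'
#' @param model_id One of `"mm"`, `"competence"`, `"penicillin"`,
#'   `"glycolysis"`.
#' @return Named numeric vector.
#' @export
benchmark_params <- function(model_id) {
  model_id <- match.arg(model_id, .BENCHMARKS)
  switch(model_id,
    mm = c(jx = 0.6, Vmax = 1.5, Km = 0.3),
    competence = c(a1 = 0.004, a2 = 0.07, a3 = 0.04, b1 = 0.82, b2 = 1854.5),
    # K1 has no established reference value; 0.1 g/L is this package's
    # documented default.  K_op = 0 and F = 0: batch operation without
    # oxygen limitation.  The trailing parameters drive the biomass and
    # substrate states (Contois growth, saturating maintenance).
    penicillin = c(mu_p = 0.005, K_p = 2e-4, K = 0.04, K1 = 0.1, F = 0,
                   K_op = 0, mu_x = 0.092, K_x = 0.15, Y_xs = 0.45,
                   Y_ps = 0.9, m_x = 0.014, K_mx = 1e-4),
    glycolysis = c(c1 = 2.5, c2 = -100, c3 = 13.6769,
                   d1 = 200, d2 = 13.6769, d3 = -6, d4 = -6,
                   e1 = 6, e2 = -64, e3 = -6, e4 = 16,
                   f1 = 64, f2 = -13, f3 = 13, f4 = -16, f5 = -100,
                   g1 = 1.3, g2 = -3.1,
                   h1 = -200, h2 = 13.6769, h3 = 128, h4 = -32, h5 = -1.28,
                   j1 = 6, j2 = -18, j3 = -100)
  )
}

# symbolic model definition: states, rational N/D per identified state and a
# plain function for the full simulation right-hand side
.model_def <- function(model_id, params = benchmark_params(model_id)) {
  model_id <- match.arg(model_id, .BENCHMARKS)
  P <- as.list(params)
  if (model_id == "mm") {
    # dx/dt = jx - Vmax x / (Km + x)  =  (jx Km + (jx - Vmax) x) / (Km + x)
    n <- 1L
    N <- .poly(rbind(0L, 1L), c(P$jx * P$Km, P$jx - P$Vmax))
    D <- .poly(rbind(0L, 1L), c(P$Km, 1))
    list(states = "x", library_states = "x", identified = "x",
         ND = list(x = list(N = N, D = D)),
         rhs = function(X) {
           x <- X[, 1L]
           cbind(P$jx - P$Vmax * x / (P$Km + x))
         })
  } else if (model_id == "competence") {
    # ComK (x1) auto-activation with a Hill term, ComS (x2) repression by
    # ComK, shared MecA-mediated degradation 1/(1 + x1 + x2)
    e <- function(i, j) { v <- c(i, j); matrix(as.integer(v), 1L) }
    hill1 <- .poly(rbind(c(0L, 0L), c(2L, 0L)), c(P$a3, 1))        # a3 + x1^2
    lin <- .poly(rbind(c(0L, 0L), c(1L, 0L), c(0L, 1L)), c(1, 1, 1)) # 1+x1+x2
    hill2 <- .poly(rbind(c(0L, 0L), c(5L, 0L)), c(1, P$b2))         # 1+b2 x1^5
    N1 <- .poly_add(
      .poly_mul(.poly_add(.poly_scale(hill1, P$a1), .poly_mono(c(2L, 0L), P$a2)), lin),
      .poly_mul(.poly_mono(c(1L, 0L), -1), hill1))
    D1 <- .poly_mul(hill1, lin)
    N2 <- .poly_add(.poly_scale(lin, P$b1),
                    .poly_mul(.poly_mono(c(0L, 1L), -1), hill2))
    D2 <- .poly_mul(hill2, lin)
    list(states = c("x1", "x2"), library_states = c("x1", "x2"),
         identified = c("x1", "x2"),
         ND = list(x1 = list(N = N1, D = D1), x2 = list(N = N2, D = D2)),
         rhs = function(X) {
           x1 <- X[, 1L]; x2 <- X[, 2L]
           cbind(P$a1 + P$a2 * x1^2 / (P$a3 + x1^2) - x1 / (1 + x1 + x2),
                 P$b1 / (1 + P$b2 * x1^5) - x2 / (1 + x1 + x2))
         })
  } else if (model_id == "penicillin") {
    if (P$F != 0) stop("penicillin generator models batch operation; F must be 0 ",
                       "(broth volume is not a state)", call. = FALSE)
    if (P$K_op != 0) stop("oxygen-limited kinetics (K_op != 0) are not modelled; ",
                          "the parameter is exposed for completeness only", call. = FALSE)
    # identified equation: product (x1) formation with substrate inhibition,
    #   dx1/dt = mu_p x2 x4 / ((K_p + x2)(1 + x2/K1)) - K x1
    # x2 (substrate) and x4 (biomass) are driven by a Contois growth
    # subsystem in the style of fed-batch penicillin simulators.
    D <- .poly_mul(.poly(rbind(c(0L, 0L, 0L), c(0L, 1L, 0L)), c(P$K_p, 1)),
                   .poly(rbind(c(0L, 0L, 0L), c(0L, 1L, 0L)), c(1, 1 / P$K1)))
    N <- .poly_add(.poly_mono(c(0L, 1L, 1L), P$mu_p),
                   .poly_scale(.poly_mul(.poly_mono(c(1L, 0L, 0L), 1), D), -P$K))
    list(states = c("x1", "x2", "x4"), library_states = c("x1", "x2", "x4"),
         identified = "x1",
         ND = list(x1 = list(N = N, D = D)),
         rhs = function(X) {
           x1 <- X[, 1L]; x2 <- X[, 2L]; x4 <- X[, 3L]
           prod_rate <- P$mu_p * x2 * x4 / ((P$K_p + x2) * (1 + x2 / P$K1))
           growth <- P$mu_x * x2 * x4 / (P$K_x * x4 + x2)
           cbind(prod_rate - P$K * x1,
                 -growth / P$Y_xs - prod_rate / P$Y_ps -
                   P$m_x * x4 * x2 / (P$K_mx + x2),
                 growth)
         })
  } else {
    # oscillatory yeast glycolysis: glucose x1, triose pool x2, BPG x3,
    # pyruvate/acetaldehyde x4, NADH x5, ATP x6, external coupling x7.
    # Three equations share the ATP-inhibition denominator 1 + beta x6^4.
    n <- 7L
    mono <- function(...) {
      e <- integer(n); idx <- list(...)
      for (ij in idx) e[ij[1L]] <- e[ij[1L]] + ij[2L]
      e
    }
    den <- function(beta) .poly(rbind(integer(n), mono(c(6L, 4L))), c(1, beta))
    m1 <- function(i) .poly_mono(mono(c(i, 1L)))
    m2 <- function(i, j) .poly_mono(if (i == j) mono(c(i, 2L)) else mono(c(i, 1L), c(j, 1L)))
    lincomb <- function(...) {
      args <- list(...)
      out <- args[[1L]]
      for (a in args[-1L]) out <- .poly_add(out, a)
      out
    }
    D1 <- den(P$c3)
    N1 <- lincomb(.poly_scale(D1, P$c1), .poly_scale(m2(1L, 6L), P$c2))
    D2 <- den(P$d2)
    N2 <- lincomb(.poly_scale(m2(1L, 6L), P$d1),
                  .poly_mul(lincomb(.poly_scale(m1(2L), P$d3),
                                    .poly_scale(m2(2L, 7L), P$d4)), D2))
    one <- .poly_const(1, n)
    N3 <- lincomb(.poly_scale(m1(2L), P$e1), .poly_scale(m1(3L), P$e2),
                  .poly_scale(m2(2L, 7L), P$e3), .poly_scale(m2(3L, 6L), P$e4))
    N4 <- lincomb(.poly_scale(m1(3L), P$f1), .poly_scale(m1(4L), P$f2),
                  .poly_scale(m1(5L), P$f3), .poly_scale(m2(3L, 6L), P$f4),
                  .poly_scale(m2(4L, 7L), P$f5))
    N5 <- lincomb(.poly_scale(m1(4L), P$g1), .poly_scale(m1(5L), P$g2))
    D6 <- den(P$h2)
    N6 <- lincomb(.poly_scale(m2(1L, 6L), P$h1),
                  .poly_mul(lincomb(.poly_scale(m1(3L), P$h3),
                                    .poly_scale(m1(6L), P$h5),
                                    .poly_scale(m2(3L, 6L), P$h4)), D6))
    N7 <- lincomb(.poly_scale(m1(2L), P$j1), .poly_scale(m2(2L, 7L), P$j2),
                  .poly_scale(m2(4L, 7L), P$j3))
    states <- paste0("x", 1:7)
    ND <- list(x1 = list(N = N1, D = D1), x2 = list(N = N2, D = D2),
               x3 = list(N = N3, D = one), x4 = list(N = N4, D = one),
               x5 = list(N = N5, D = one), x6 = list(N = N6, D = D6),
               x7 = list(N = N7, D = one))
    list(states = states, library_states = states, identified = states,
         ND = ND,
         rhs = function(X) {
           x1 <- X[, 1L]; x2 <- X[, 2L]; x3 <- X[, 3L]; x4 <- X[, 4L]
           x5 <- X[, 5L]; x6 <- X[, 6L]; x7 <- X[, 7L]
           hx <- x1 * x6 / (1 + P$c3 * x6^4)
           cbind(P$c1 + P$c2 * hx,
                 P$d1 * hx + P$d3 * x2 + P$d4 * x2 * x7,
                 P$e1 * x2 + P$e2 * x3 + P$e3 * x2 * x7 + P$e4 * x3 * x6,
                 P$f1 * x3 + P$f2 * x4 + P$f3 * x5 + P$f4 * x3 * x6 + P$f5 * x4 * x7,
                 P$g1 * x4 + P$g2 * x5,
                 P$h1 * hx + P$h3 * x3 + P$h5 * x6 + P$h4 * x3 * x6,
                 P$j1 * x2 + P$j2 * x2 * x7 + P$j3 * x4 * x7)
         })
  }
}

#' Benchmark right-hand side
#'
#' Evaluates the time derivative of the benchmark system at a state vector
#' (or at every row of a state matrix).  For the penicillin system the state
#' is `(x1, x2, x4)` = (penicillin, substrate, biomass).
#'
#' @param model_id Benchmark identifier.
#' @param x Numeric state vector, or a matrix with one state per column.
#' @param params Named parameter vector; defaults to the true values.
#' @return Derivative vector (or matrix, matching `x`).
#' @export
#' @examples
#' benchmark_rhs("mm", 0)     # = jx: the rational term vanishes at x = 0
#' benchmark_rhs("mm", 0.2)   # = 0: the equilibrium substrate concentration
benchmark_rhs <- function(model_id, x, params = benchmark_params(model_id)) {
  def <- .model_def(model_id, params)
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(X) != length(def$states)) {
    stop(sprintf("'%s' has %d states, got %d", model_id, length(def$states), ncol(X)))
  }
  for (s in def$identified) {
    dval <- .poly_eval(def$ND[[s]]$D, X)
    if (any(dval == 0)) {
      stop(sprintf("denominator of the %s equation vanishes at the supplied state", s))
    }
  }
  out <- def$rhs(X)
  colnames(out) <- def$states
  if (vec) drop(out) else out
}

#' Benchmark study design
#'
#' Bundles everything needed to simulate a benchmark: parameters, the time
#' grid, the number of trajectories and the initial-condition sampler.  The
#' defaults are the study conditions of the reference experiments:
#' Michaelis-Menten from two starts (x0 = 0.5, 2.0) over 0..20 s sampled every
#' second with a degree-4 library; competence from 20 uniform starts on
#' \[0,1\]^2 over 0..50 s with a degree-6 library; penicillin from 20 starts
#' over 100 h of hourly sampling with a degree-3 library in (x1, x2, x4);
#' glycolysis from 450 uniform starts within literature concentration ranges
#' over 0..5 at 0.1 time units with a degree-6 library.
#'
#' @param model_id Benchmark identifier.
#' @param params Named parameters (defaults to [benchmark_params()]).
#' @param degree Library degree.
#' @param t_span Length-2 numeric, integration window.
#' @param dt Sampling interval (> 0).
#' @param n_trajectories Number of trajectories (>= 1).
#' @param x0 Optional matrix of initial conditions (one row per trajectory);
#'   overrides the sampler.
#' @param ic_lower,ic_upper Bounds of the uniform initial-condition sampler.
#' @param rtol,atol Integrator tolerances (tight by default so that
#'   trajectory error never dominates identification error).
#' @return An object of class `"benchmark_spec"`.
#' @export
benchmark_spec <- function(model_id,
                           params = benchmark_params(model_id),
                           degree = NULL, t_span = NULL, dt = NULL,
                           n_trajectories = NULL, x0 = NULL,
                           ic_lower = NULL, ic_upper = NULL,
                           rtol = 1e-12, atol = 1e-12) {
  model_id <- match.arg(model_id, .BENCHMARKS)
  def <- .model_def(model_id, params)
  dflt <- switch(model_id,
    mm = list(degree = 4L, t_span = c(0, 20), dt = 1, n_trajectories = 2L,
              x0 = matrix(c(0.5, 2.0), 2L, 1L), ic_lower = 0.1, ic_upper = 2.5),
    competence = list(degree = 6L, t_span = c(0, 50), dt = 1,
                      n_trajectories = 20L, x0 = NULL,
                      ic_lower = c(0, 0), ic_upper = c(1, 1)),
    penicillin = list(degree = 3L, t_span = c(0, 100), dt = 1,
                      n_trajectories = 20L, x0 = NULL,
                      ic_lower = c(0, 4, 0.05), ic_upper = c(1, 6, 0.15)),
    glycolysis = list(degree = 6L, t_span = c(0, 5), dt = 0.1,
                      n_trajectories = 450L, x0 = NULL,
                      ic_lower = c(0.15, 0.19, 0.04, 0.10, 0.08, 0.14, 0.05),
                      ic_upper = c(1.60, 2.16, 0.20, 0.35, 0.30, 2.67, 0.10))
  )
  spec <- list(model_id = model_id, params = params,
               state_names = def$states, library_states = def$library_states,
               identified_states = def$identified,
               degree = as.integer(degree %||% dflt$degree),
               t_span = t_span %||% dflt$t_span,
               dt = dt %||% dflt$dt,
               n_trajectories = as.integer(n_trajectories %||% dflt$n_trajectories),
               x0 = x0 %||% dflt$x0,
               ic_lower = ic_lower %||% dflt$ic_lower,
               ic_upper = ic_upper %||% dflt$ic_upper,
               rtol = rtol, atol = atol)
  stopifnot(spec$degree >= 1L, spec$dt > 0, spec$n_trajectories >= 1L,
            all(spec$library_states %in% spec$state_names))
  if (!is.null(spec$x0)) {
    spec$x0 <- matrix(spec$x0, ncol = length(def$states))
    spec$n_trajectories <- nrow(spec$x0)
  }
  class(spec) <- "benchmark_spec"
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.benchmark_spec <- function(x, ...) {
  cat(sprintf("Benchmark '%s': %d state(s), degree-%d library, t in [%g, %g], dt = %g, %d trajectories\n",
              x$model_id, length(x$state_names), x$degree,
              x$t_span[1], x$t_span[2], x$dt, x$n_trajectories))
  invisible(x)
}

#' Simulate a benchmark system
#'
#' Integrates the benchmark from its initial conditions with a stiff-capable
#' solver and stacks the sampled trajectories row-wise.  The derivative
#' matrix `Xdot` is filled by exact evaluation of the model right-hand side at
#' the sampled states, so the implicit relation holds at every row to
#' round-off; use [add_noise()] followed by [compute_derivatives()] to emulate
#' measured data instead.
#'
#' @param spec A `"benchmark_spec"`.
#' @param seed Integer seed for the initial-condition sampler (ignored when
#'   `spec$x0` is given).  A fixed seed makes the dataset reproducible.
#' @return A `"rode_dataset"` with attribute `"spec"`.
#' @export
simulate_benchmark <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "benchmark_spec"))
  def <- .model_def(spec$model_id, spec$params)
  n <- length(def$states)
  if (!is.null(spec$x0)) {
    X0 <- spec$x0
  } else {
    set.seed(seed)
    X0 <- t(replicate(spec$n_trajectories,
                      stats::runif(n, spec$ic_lower, spec$ic_upper)))
    X0 <- matrix(X0, ncol = n)
  }
  times <- seq(spec$t_span[1], spec$t_span[2], by = spec$dt)
  fn <- function(t, y, p) list(drop(def$rhs(matrix(y, 1L))))
  pieces <- vector("list", nrow(X0))
  for (i in seq_len(nrow(X0))) {
    sol <- try(deSolve::ode(X0[i, ], times, fn, NULL, method = "lsoda",
                            rtol = spec$rtol, atol = spec$atol), silent = TRUE)
    if (inherits(sol, "try-error") || nrow(sol) < length(times) || any(!is.finite(sol))) {
      tfail <- if (inherits(sol, "try-error")) NA_real_ else sol[nrow(sol), 1L]
      stop(sprintf("integration of trajectory %d failed near t = %s", i,
                   format(tfail)), call. = FALSE)
    }
    pieces[[i]] <- unname(sol[, -1L, drop = FALSE])
  }
  X <- do.call(rbind, pieces)
  colnames(X) <- def$states
  out <- rode_dataset(X, rep(times, nrow(X0)), def$rhs(X),
                      rep(seq_len(nrow(X0)), each = length(times)))
  attr(out, "spec") <- spec
  out
}

#' Ground-truth implicit coefficient vector
#'
#' Expands the implicit identity `dx_k/dt * D(x) - N(x) = 0` of a benchmark
#' equation over a library term ordering.  The plain-monomial block receives
#' `-N` and the derivative-paired block receives `D`, the vector is scaled to
#' unit Euclidean norm and its sign fixed so the largest-magnitude entry is
#' positive — the same conventions as an identified null vector, so the two
#' are directly comparable.
#'
#' @param model_id Benchmark identifier.
#' @param state Identified state (name or index among the model's states).
#' @param terms Library term set (a `"rode_terms"` with derivative pairing);
#'   defaults to the benchmark's standard library.
#' @param params Named parameters.
#' @return An object of class `"rode_truth"`: list with `xi`, `support`,
#'   `terms`, `state` and `model_id`.
#' @export
#' @examples
#' tr <- implicit_truth("mm", "x")
#' term_labels(tr$terms)[tr$support]   # 1, x, dx, x*dx
implicit_truth <- function(model_id, state = 1L, terms = NULL,
                           params = benchmark_params(model_id)) {
  def <- .model_def(model_id, params)
  if (is.numeric(state)) state <- def$identified[state]
  if (!state %in% def$identified) {
    stop(sprintf("state '%s' is not an identified equation of '%s'", state, model_id))
  }
  if (is.null(terms)) {
    spec <- benchmark_spec(model_id, params = params)
    terms <- polynomial_terms(def$library_states, spec$degree, deriv_state = state)
  }
  stopifnot(inherits(terms, "rode_terms"), !is.null(terms$deriv_state))
  ND <- def$ND[[state]]
  xi <- numeric(length(terms))
  xi[.poly_indices(ND$N, terms, with_deriv = FALSE)] <- -ND$N$coef
  xi[.poly_indices(ND$D, terms, with_deriv = TRUE)] <- ND$D$coef
  if (all(xi == 0)) stop("implicit expansion is identically zero")
  xi <- xi / sqrt(sum(xi^2))
  if (xi[which.max(abs(xi))] < 0) xi <- -xi
  structure(list(xi = xi, support = which(xi != 0), terms = terms,
                 state = state, model_id = model_id),
            class = "rode_truth")
}

#' @export
print.rode_truth <- function(x, ...) {
  cat(sprintf("Implicit truth for '%s', equation d%s: %d active of %d terms\n",
              x$model_id, x$state, length(x$support), length(x$xi)))
  lab <- term_labels(x$terms)
  cat(" ", paste(sprintf("%s (%.4g)", lab[x$support], x$xi[x$support]),
                 collapse = "  "), "\n")
  invisible(x)
}

#' Add Gaussian measurement noise to the states
#'
#' Adds i.i.d. Gaussian noise of standard deviation `sigma` to every entry of
#' the state matrix.  Sampling times and trajectory bookkeeping are kept;
#' stored derivatives are dropped, because they no longer match the perturbed
#' states and must be re-estimated (see [compute_derivatives()]).
#'
#' @param data A `"rode_dataset"`.
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Integer seed; the same seed reproduces the same noise.
#' @return A `"rode_dataset"` without derivatives.
#' @export
add_noise <- function(data, sigma, seed = 1L) {
  stopifnot(inherits(data, "rode_dataset"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    stop("sigma must be a single non-negative number")
  }
  X <- data$X
  if (sigma > 0) {
    set.seed(seed)
    X <- X + matrix(stats::rnorm(length(X), 0, sigma), nrow(X), ncol(X))
  }
  out <- rode_dataset(X, data$t, NULL, data$trajectory, data$states)
  attr(out, "spec") <- attr(data, "spec")
  out
}

#' Read and write benchmark specifications
#'
#' Serialises a `"benchmark_spec"` to YAML (default) or JSON, chosen by file
#' extension.
#'
#' @param spec A `"benchmark_spec"`.
#' @param file Path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_benchmark_spec` returns `file` invisibly;
#'   `read_benchmark_spec` returns a `"benchmark_spec"`.
#' @export
write_benchmark_spec <- function(spec, file) {
  stopifnot(inherits(spec, "benchmark_spec"))
  lst <- unclass(spec)
  lst$params <- as.list(lst$params)
  if (!is.null(lst$x0)) lst$x0 <- as.data.frame(lst$x0)
  if (grepl("\\.json$", file)) {
    jsonlite::write_json(lst, file, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, file)
  }
  invisible(file)
}

#' @rdname write_benchmark_spec
#' @export
read_benchmark_spec <- function(file) {
  lst <- if (grepl("\\.json$", file)) jsonlite::read_json(file, simplifyVector = TRUE)
         else yaml::read_yaml(file)
  x0 <- lst$x0
  if (!length(x0)) x0 <- NULL
  if (!is.null(x0)) x0 <- as.matrix(as.data.frame(x0))
  benchmark_spec(lst$model_id, params = unlist(lst$params),
                 degree = lst$degree, t_span = as.numeric(lst$t_span),
                 dt = lst$dt, n_trajectories = lst$n_trajectories, x0 = x0,
                 ic_lower = as.numeric(lst$ic_lower),
                 ic_upper = as.numeric(lst$ic_upper),
                 rtol = lst$rtol, atol = lst$atol)
}
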