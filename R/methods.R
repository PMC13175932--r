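#' @export
print.rational_ode <- function(x, digits = 6, ...) {
  cat("Rational ODE identified by null-space analysis\n")
  cat(sprintf("  equation: %s\n", format(x$model, digits = digits)))
  cat(sprintf("  support: %d of %d library terms (lambda = %g, %s back end)\n",
              length(x$support), x$q, x$lambda, x$selection))
  if (!is.null(x$hypothesis)) {
    h <- x$hypothesis
    cat(sprintf("  accepted sub-library: degree <= %d in (%s), q = %d, held-out error %.3g\n",
                h$degree, paste(h$states, collapse = ", "), h$q, h$heldout_error))
  }
  invisible(x)
}

#' @export
summary.rational_ode <- function(object, ...) {
  sv <- object$nullvector$singular_values
  lab <- term_labels(object$terms)
  structure(list(fit = object,
                 equation = format(object$model),
                 support_terms = data.frame(term = lab[object$support],
                                            coefficient = object$nullvector$xi[object$support]),
                 sigma_min = min(sv), sigma_max = max(sv),
                 sigma_gap = if (length(sv) > 1L) sort(sv)[2L] / max(min(sv), 1e-300) else NA,
                 cluster_dim = object$nullvector$cluster_dim,
                 rms_residual = sqrt(mean(object$residuals^2))),
            class = "summary.rational_ode")
}

#' @export
print.summary.rational_ode <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  singular values: min %.3g, max %.3g (ratio %.3g); near-null cluster dimension %d\n",
              x$sigma_min, x$sigma_max, x$sigma_min / x$sigma_max, x$cluster_dim))
  cat(sprintf("  rms implicit residual: %.3g\n", x$rms_residual))
  cat("  active terms:\n")
  print(x$support_terms, row.names = FALSE)
  invisible(x)
}

#' Extract coefficients of a fitted rational ODE
#'
#' @param object A `"rational_ode"`.
#' @param type `"xi"` for the full unit-norm implicit coefficient vector
#'   (named by term), or `"model"` for the numerator / denominator
#'   coefficients after pivot normalisation.
#' @param ... Unused.
#' @export
coef.rational_ode <- function(object, type = c("xi", "model"), ...) {
  type <- match.arg(type)
  if (type == "xi") {
    stats::setNames(object$nullvector$xi, term_labels(object$terms))
  } else {
    lab <- term_labels(object$model$monomials)
    list(numerator = stats::setNames(object$model$numer, lab),
         denominator = stats::setNames(object$model$denom, lab))
  }
}

#' @export
predict.rational_ode <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$data)) stop("fit was made with keep_data = FALSE; supply newdata")
    newdata <- object$data$X
  } else if (inherits(newdata, "rode_dataset")) {
    newdata <- newdata$X
  }
  predict(object$model, newdata)
}

#' @export
fitted.rational_ode <- function(object, ...) predict(object)

#' Residuals of a fitted rational ODE
#'
#' @param object A `"rational_ode"`.
#' @param type `"implicit"` returns the library residual `B xi` row by row;
#'   `"derivative"` returns the difference between the stored derivatives
#'   and the model's predicted `dx/dt`.
#' @param ... Unused.
#' @export
residuals.rational_ode <- function(object, type = c("implicit", "derivative"), ...) {
  type <- match.arg(type)
  if (type == "implicit") return(object$residuals)
  if (is.null(object$data)) stop("fit was made with keep_data = FALSE")
  object$data$Xdot[, object$state] - predict(object)
}

#' Plot diagnostics of a fitted rational ODE
#'
#' Left panel: the singular-value spectrum of the (accepted) library on a
#' logarithmic scale, with the null direction highlighted.  Right panel: the
#' implicit coefficient vector as a stem plot over the library terms, with
#' the sparsification threshold marked.
#'
#' @param x A `"rational_ode"`.
#' @param ... Passed to the underlying plot calls.
#' @export
plot.rational_ode <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4.5, 4.5, 2, 1))
  on.exit(graphics::par(op))
  sv <- sort(x$nullvector$singular_values, decreasing = TRUE)
  graphics::plot(seq_along(sv), pmax(sv, .Machine$double.xmin), log = "y",
                 xlab = "index", ylab = "singular value",
                 main = "library spectrum", pch = 19, cex = 0.6, ...)
  graphics::points(length(sv), pmax(sv[length(sv)], .Machine$double.xmin),
                   col = 2, pch = 19)
  xi <- x$nullvector$xi
  graphics::plot(seq_along(xi), xi, type = "h",
                 xlab = "library term", ylab = "coefficient",
                 main = sprintf("null vector (support %d)", length(x$support)), ...)
  graphics::abline(h = c(-x$lambda, x$lambda), lty = 3, col = "grey40")
  graphics::points(x$support, xi[x$support], pch = 19, cex = 0.6, col = 2)
  invisible(x)
}

#' Simulate a fitted rational ODE
#'
#' Integrates the identified equation.  Only available when the fit's
#' library covers all states of a self-contained system (for a one-state
#' model, or combined with further fits via [simulate_identified()]).
#'
#' @param object A `"rational_ode"` whose library has a single state.
#' @param nsim,seed Unused (the identified model is deterministic).
#' @param x0 Initial condition.
#' @param times Output time grid.
#' @param ... Passed to [simulate_identified()].
#' @export
simulate.rational_ode <- function(object, nsim = 1, seed = NULL,
                                  x0, times, ...) {
  if (length(object$states) != 1L) {
    stop("this fit covers one equation of a ", length(object$states),
         "-state system; integrate a complete set with simulate_identified()")
  }
  simulate_identified(object, x0, times, ...)
}
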