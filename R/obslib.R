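#' Build the observational library
#'
#' Evaluates every monomial of the library states up to the requested degree
#' on the rows of the dataset, producing the polynomial feature block, and
#' pairs it with the same block multiplied elementwise by the derivative of
#' the identified state.  The resulting matrix `B = [Theta(X), dx_k * Theta(X)]`
#' has `q = 2 * choose(n + d, d)` columns; a coefficient vector in its null
#' space encodes an implicit rational relation `dx_k * D(x) = N(x)`.
#'
#' @param data A `"rode_dataset"` with derivatives present.
#' @param state Identified state, by name or index.
#' @param degree Maximum monomial degree.
#' @param states States entering the library (default: all states).
#' @return An object of class `"rode_library"`: list with the matrix `B`,
#'   the `"rode_terms"` term set `terms`, `state`, `states` and `degree`.
#' @export
#' @examples
#' # the Michaelis-Menten library has 10 columns: 1, x, ..., x^4, dx, ..., x^4 dx
observational_library <- function(data, state = 1L, degree, states = NULL) {
  stopifnot(inherits(data, "rode_dataset"))
  if (is.null(data$Xdot)) {
    stop("dataset has no derivatives; run compute_derivatives() first")
  }
  if (is.numeric(state)) state <- data$states[state]
  if (!state %in% data$states) stop("unknown state '", state, "'")
  states <- states %||% data$states
  stopifnot(all(states %in% data$states))
  terms <- polynomial_terms(states, degree, deriv_state = state)
  Xsub <- data$X[, states, drop = FALSE]
  m <- length(terms) %/% 2L
  Theta <- .eval_monomials(Xsub, terms$exponents[seq_len(m), , drop = FALSE])
  xd <- data$Xdot[, state]
  B <- cbind(Theta, xd * Theta)
  colnames(B) <- term_labels(terms)
  structure(list(B = B, terms = terms, state = state, states = states,
                 degree = as.integer(degree)),
            class = "rode_library")
}

#' @export
print.rode_library <- function(x, ...) {
  cat(sprintf("Observational library for d%s: %d rows x %d columns (degree <= %d in %s)\n",
              x$state, nrow(x$B), ncol(x$B), x$degree,
              paste(x$states, collapse = ", ")))
  invisible(x)
}

#' @export
dim.rode_library <- function(x) dim(x$B)

#' Export an observational library to CSV
#'
#' Column headers are the human-readable term labels; mainly useful for
#' debugging small libraries.
#'
#' @param library A `"rode_library"`.
#' @param file Output path.
#' @export
write_library <- function(library, file) {
  stopifnot(inherits(library, "rode_library"))
  utils::write.csv(as.data.frame(library$B), file, row.names = FALSE)
  invisible(file)
}
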