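#' Enumerate polynomial library terms
#'
#' Generates all monomials in the given states up to a total degree, in
#' graded-lexicographic order: terms are sorted by total degree, and within a
#' degree the exponent of the first state decreases first (so for two states
#' the quadratic block reads x1^2, x1*x2, x2^2).  The constant term comes
#' first.  This ordering is a pure function of `states` and `degree`, which
#' keeps coefficient indices stable across runs.
#'
#' The number of monomials of total degree at most d in n states is
#' choose(n + d, d).
#'
#' @param states Either the number of states or a character vector of state
#'   names (names are used in term labels).
#' @param degree Maximum total polynomial degree (>= 0).
#' @param deriv_state Optional name of a derivative variable.  When supplied,
#'   the term set is doubled: every monomial appears once plainly and once
#'   multiplied by the derivative, in the same order, which is the column
#'   layout of an observational library.
#' @return An object of class `"rode_terms"`: a list with `exponents` (matrix,
#'   one row per term), `with_deriv` (logical), `states`, `degree` and
#'   `deriv_state`.
#' @seealso [observational_library()], [term_labels()]
#' @export
#' @examples
#' polynomial_terms("x", 4)            # 1, x, x^2, x^3, x^4
#' length(polynomial_terms(2, 2))      # 6 monomials, including x1*x2
polynomial_terms <- function(states, degree, deriv_state = NULL) {
  if (is.numeric(states) && length(states) == 1L) {
    states <- paste0("x", seq_len(states))
  }
  states <- as.character(states)
  n <- length(states)
  stopifnot(n >= 1L, degree >= 0L)
  degree <- as.integer(degree)

  E <- .monomial_exponents(n, degree)
  colnames(E) <- states
  with_deriv <- rep(FALSE, nrow(E))
  if (!is.null(deriv_state)) {
    E <- rbind(E, E)
    with_deriv <- rep(c(FALSE, TRUE), each = nrow(E) / 2L)
  }
  structure(
    list(exponents = E, with_deriv = with_deriv, states = states,
         degree = degree, deriv_state = deriv_state),
    class = "rode_terms"
  )
}

# all exponent multi-indices with total degree <= degree, graded-lex
.monomial_exponents <- function(n, degree) {
  exact <- function(nn, dd) {
    if (nn == 1L) return(matrix(dd, 1L, 1L))
    out <- list()
    for (e in dd:0) out[[length(out) + 1L]] <- cbind(e, exact(nn - 1L, dd - e))
    do.call(rbind, out)
  }
  E <- do.call(rbind, lapply(0:degree, function(d) exact(n, d)))
  dimnames(E) <- NULL
  storage.mode(E) <- "integer"
  E
}

#' @export
length.rode_terms <- function(x) nrow(x$exponents)

#' Human-readable labels for library terms
#'
#' @param terms A `"rode_terms"` object.
#' @return Character vector such as `"1"`, `"x1^2*x2"` or `"x1*dx2"`.
#' @export
term_labels <- function(terms) {
  stopifnot(inherits(terms, "rode_terms"))
  E <- terms$exponents
  lab <- apply(E, 1L, function(e) {
    nz <- which(e > 0L)
    if (!length(nz)) return("1")
    paste(ifelse(e[nz] == 1L, terms$states[nz],
                 paste0(terms$states[nz], "^", e[nz])), collapse = "*")
  })
  if (!is.null(terms$deriv_state)) {
    d <- paste0("d", terms$deriv_state)
    lab[terms$with_deriv] <- ifelse(lab[terms$with_deriv] == "1", d,
                                    paste0(lab[terms$with_deriv], "*", d))
  }
  lab
}

#' @export
print.rode_terms <- function(x, ...) {
  cat(sprintf("Library terms: %d terms in (%s), degree <= %d%s\n",
              length(x), paste(x$states, collapse = ", "), x$degree,
              if (is.null(x$deriv_state)) "" else
                sprintf(", paired with d%s", x$deriv_state)))
  lab <- term_labels(x)
  if (length(lab) > 12L) lab <- c(lab[1:12], sprintf("... (%d more)", length(lab) - 12L))
  cat(" ", paste(lab, collapse = "  "), "\n")
  invisible(x)
}

#' @export
as.character.rode_terms <- function(x, ...) term_labels(x)

# total degree of every term (the monomial degree; derivative pairing does
# not change the graded level used by the minimal-degree rules)
.term_degrees <- function(terms) as.integer(rowSums(terms$exponents))

# evaluate the monomial block of a term set on a state matrix
.eval_monomials <- function(X, E) {
  p <- nrow(X)
  Th <- matrix(1, p, nrow(E))
  for (j in seq_len(nrow(E))) {
    e <- E[j, ]
    for (i in which(e > 0L)) Th[, j] <- Th[, j] * X[, i]^e[i]
  }
  Th
}

## -- minimal sparse polynomial arithmetic (exponent matrix + coefficients) --
## used to expand the implicit form  dx_k * D(x) - N(x)  symbolically

.poly <- function(E, coef) {
  keep <- coef != 0
  list(E = E[keep, , drop = FALSE], coef = coef[keep])
}

.poly_const <- function(c0, n) .poly(matrix(0L, 1L, n), c0)

.poly_mono <- function(expnt, c0 = 1) .poly(matrix(as.integer(expnt), 1L), c0)

.poly_add <- function(p1, p2) {
  E <- rbind(p1$E, p2$E)
  coef <- c(p1$coef, p2$coef)
  key <- apply(E, 1L, paste, collapse = ",")
  agg <- tapply(coef, key, sum)
  keyu <- names(agg)
  Eu <- do.call(rbind, lapply(strsplit(keyu, ","), as.integer))
  .poly(Eu, as.numeric(agg))
}

.poly_scale <- function(p, s) .poly(p$E, p$coef * s)

.poly_mul <- function(p1, p2) {
  E <- p1$E[rep(seq_along(p1$coef), each = length(p2$coef)), , drop = FALSE] +
    p2$E[rep(seq_along(p2$coef), times = length(p1$coef)), , drop = FALSE]
  coef <- rep(p1$coef, each = length(p2$coef)) * rep(p2$coef, length(p1$coef))
  key <- apply(E, 1L, paste, collapse = ",")
  agg <- tapply(coef, key, sum)
  Eu <- do.call(rbind, lapply(strsplit(names(agg), ","), as.integer))
  .poly(Eu, as.numeric(agg))
}

# evaluate a sparse polynomial on rows of a state matrix
.poly_eval <- function(p, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  out <- numeric(nrow(X))
  for (j in seq_along(p$coef)) {
    v <- rep(p$coef[j], nrow(X))
    e <- p$E[j, ]
    for (i in which(e > 0L)) v <- v * X[, i]^e[i]
    out <- out + v
  }
  out
}

# index of each polynomial term inside a term set (block chosen by with_deriv)
.poly_indices <- function(p, terms, with_deriv) {
  key_terms <- apply(terms$exponents, 1L, paste, collapse = ",")
  key_terms[terms$with_deriv != with_deriv] <- NA
  key_p <- apply(p$E, 1L, paste, collapse = ",")
  idx <- match(key_p, key_terms)
  if (anyNA(idx)) {
    stop("term ordering has insufficient degree: missing ",
         paste(key_p[is.na(idx)], collapse = "; "), call. = FALSE)
  }
  idx
}
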