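#' Structural (support) error
#'
#' L0-based score comparing the set of identified active terms to the true
#' support:
#' `e = 1 - |S_true n S_id| / (|S_true| + |S_id \\ S_true|)`.
#' It is 0 exactly when the supports coincide, increases when a true term is
#' missed or a spurious term is added, and is bounded by 1.  With four true
#' terms, finding three of them (one missing, none spurious) scores 0.25 and
#' finding all four plus one spurious term scores 0.2.
#'
#' @param s_true True support: vector of term indices or labels (non-empty).
#' @param s_identified Identified support, over the same term universe.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' structural_error(1:4, 1:3)        # 0.25
#' structural_error(1:4, 1:5)        # 0.2
#' structural_error(1:4, 1:4)        # 0
structural_error <- function(s_true, s_identified) {
  s_true <- unique(s_true)
  s_identified <- unique(s_identified)
  if (!length(s_true)) stop("the true support must be non-empty")
  hits <- length(intersect(s_true, s_identified))
  spurious <- length(setdiff(s_identified, s_true))
  1 - hits / (length(s_true) + spurious)
}

#' Relative coefficient-vector error
#'
#' Relative Euclidean error `||xi_true - xi_est||_2 / ||xi_true||_2` between
#' two implicit coefficient vectors over the same term ordering.  Both
#' vectors are first normalised to unit norm, and the sign of the estimate is
#' chosen to minimise the error, because a null vector is only defined up to
#' scale and sign.
#'
#' @param xi_true,xi_est Numeric vectors of equal length; `xi_true` must be
#'   non-zero.
#' @return Non-negative number.
#' @export
parameter_error <- function(xi_true, xi_est) {
  if (length(xi_true) != length(xi_est)) stop("coefficient vectors differ in length")
  nt <- sqrt(sum(xi_true^2))
  if (nt == 0) stop("xi_true is identically zero")
  xt <- xi_true / nt
  ne <- sqrt(sum(xi_est^2))
  if (ne == 0) return(1)
  xe <- xi_est / ne
  min(sqrt(sum((xt - xe)^2)), sqrt(sum((xt + xe)^2)))
}

#' Relative Frobenius parameter error
#'
#' `||est - true||_F / ||true||_F` over aligned named parameters.  When both
#' arguments are named, the estimate is re-ordered to the truth's names and
#' missing parameters raise an error.  With `sign_insensitive = TRUE` the
#' magnitudes are compared instead, for situations where reported
#' coefficients carry arbitrary signs.
#'
#' @param true,est Named numeric vectors (or matrices) of parameters.
#' @param sign_insensitive Compare absolute values.
#' @return Non-negative number.
#' @export
#' @examples
#' relative_frobenius(c(Km = 0.3), c(Km = 0.33))   # 0.1
relative_frobenius <- function(true, est, sign_insensitive = FALSE) {
  true_v <- as.numeric(true)
  if (!is.null(names(true)) && !is.null(names(est))) {
    if (!all(names(true) %in% names(est))) {
      stop("missing parameters: ", paste(setdiff(names(true), names(est)), collapse = ", "))
    }
    est_v <- as.numeric(est[names(true)])
  } else {
    if (length(true) != length(est)) stop("parameter sets differ in length")
    est_v <- as.numeric(est)
  }
  nt <- sqrt(sum(true_v^2))
  if (nt == 0) stop("the true parameter vector is identically zero")
  if (sign_insensitive) {
    true_v <- abs(true_v)
    est_v <- abs(est_v)
  }
  sqrt(sum((est_v - true_v)^2)) / nt
}
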