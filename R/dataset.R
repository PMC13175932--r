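#' Stacked time-series dataset
#'
#' Container for one or more trajectories of a dynamical system: a state
#' matrix `X` (one row per sampling time), the sampling times `t`, an optional
#' matrix of state derivatives `Xdot` aligned row-by-row with `X`, and an
#' integer `trajectory` index mapping each row to the trajectory it came from.
#' Within a trajectory the sampling times must be strictly increasing.
#'
#' @param X Numeric matrix (p x n) of states; column names become state names.
#' @param t Numeric vector of length p of sampling times.
#' @param Xdot Optional p x n matrix of derivatives (same layout as `X`).
#' @param trajectory Integer vector of length p; defaults to a single
#'   trajectory.
#' @param states Optional character vector of state names, used when `X` has
#'   no column names.
#' @return An object of class `"rode_dataset"`.
#' @export
rode_dataset <- function(X, t, Xdot = NULL, trajectory = NULL, states = NULL) {
  X <- as.matrix(X)
  if (is.null(states)) states <- colnames(X)
  if (is.null(states)) states <- paste0("x", seq_len(ncol(X)))
  colnames(X) <- states
  p <- nrow(X)
  if (length(t) != p) stop("length(t) must equal nrow(X)")
  if (is.null(trajectory)) trajectory <- rep(1L, p)
  if (length(trajectory) != p) stop("length(trajectory) must equal nrow(X)")
  trajectory <- as.integer(trajectory)
  if (!is.null(Xdot)) {
    Xdot <- as.matrix(Xdot)
    if (!all(dim(Xdot) == dim(X))) stop("Xdot must have the same shape as X")
    colnames(Xdot) <- states
  }
  for (id in unique(trajectory)) {
    ti <- t[trajectory == id]
    if (any(diff(ti) <= 0)) {
      stop("sampling times must be strictly increasing within trajectory ", id)
    }
  }
  structure(list(X = X, t = as.numeric(t), Xdot = Xdot,
                 trajectory = trajectory, states = states),
            class = "rode_dataset")
}

#' @export
print.rode_dataset <- function(x, ...) {
  cat(sprintf("Time-series dataset: %d rows, %d states (%s), %d trajectories%s\n",
              nrow(x$X), length(x$states), paste(x$states, collapse = ", "),
              length(unique(x$trajectory)),
              if (is.null(x$Xdot)) ", derivatives absent" else ", derivatives present"))
  invisible(x)
}

#' @export
dim.rode_dataset <- function(x) dim(x$X)

#' @export
as.data.frame.rode_dataset <- function(x, ...) {
  df <- data.frame(t = x$t, trajectory_id = x$trajectory)
  df <- cbind(df, as.data.frame(x$X))
  if (!is.null(x$Xdot)) {
    Xd <- as.data.frame(x$Xdot)
    names(Xd) <- paste0("xdot_", x$states)
    df <- cbind(df, Xd)
  }
  df
}

# row subsetting that keeps all components aligned
.dataset_rows <- function(data, rows) {
  rode_dataset(data$X[rows, , drop = FALSE], data$t[rows],
               if (is.null(data$Xdot)) NULL else data$Xdot[rows, , drop = FALSE],
               data$trajectory[rows], data$states)
}

#' Read and write datasets as CSV
#'
#' The file layout has columns `t`, `trajectory_id`, one column per state and
#' (optionally) one `xdot_<state>` column per state.
#'
#' @param data A `"rode_dataset"`.
#' @param file Path to a CSV file.
#' @return `write_dataset` returns `file` invisibly; `read_dataset` returns a
#'   `"rode_dataset"`.
#' @export
write_dataset <- function(data, file) {
  stopifnot(inherits(data, "rode_dataset"))
  utils::write.csv(as.data.frame(data), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(file) {
  df <- utils::read.csv(file)
  if (!all(c("t", "trajectory_id") %in% names(df))) {
    stop("CSV must contain columns 't' and 'trajectory_id'")
  }
  dcols <- grep("^xdot_", names(df), value = TRUE)
  scols <- setdiff(names(df), c("t", "trajectory_id", dcols))
  Xdot <- NULL
  if (length(dcols)) {
    Xdot <- as.matrix(df[dcols])
    colnames(Xdot) <- sub("^xdot_", "", dcols)
    Xdot <- Xdot[, scols, drop = FALSE]
  }
  rode_dataset(as.matrix(df[scols]), df$t, Xdot, df$trajectory_id, scols)
}
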