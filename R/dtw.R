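#' Local distance matrix between two scalar time series
#'
#' Entry (m, n) is the Euclidean distance `|x[m] - y[n]|` between sample m
#' of `x` and sample n of `y`; this is the pattern-matching cost field that
#' dynamic time warping accumulates over.
#'
#' @param x,y numeric vectors (one electrode's feature time series).
#' @return an M x N numeric matrix of nonnegative local distances.
#' @examples
#' local_distance_matrix(c(1, 2), c(2, 4))
#' @export
local_distance_matrix <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L)
    stop("'x' and 'y' must each contain at least one sample")
  if (anyNA(x) || anyNA(y)) stop("NA values are not allowed in the series")
  abs(outer(as.numeric(x), as.numeric(y), "-"))
}

#' Dynamic time warping alignment of two scalar time series
#'
#' Finds the monotone warping path (steps down, right or diagonal, from
#' (1, 1) to (M, N)) minimising the accumulated local distance
#' `sum |x[phi_x(k)] - y[phi_y(k)]|`, by dynamic programming. The reported
#' distance is the average accumulated distortion: the minimal accumulated
#' distance divided by the path length K (set `normalize = FALSE` for the
#' raw accumulated distance). Division by K also compensates for unequal
#' series lengths. Equal-cost predecessors are resolved in favour of the
#' diagonal step, which affects the reported path but not the distance.
#'
#' DTW distance is symmetric in its arguments and zero exactly when the
#' aligned samples are pairwise equal, but it is not a metric (no triangle
#' inequality).
#'
#' @param x,y numeric vectors of length >= 1.
#' @param normalize divide the accumulated distance by the path length K?
#' @param band optional Sakoe-Chiba band half-width in samples around the
#'   (rescaled) diagonal; `NULL` (default) applies no global constraint.
#' @return an object of class `"dtw_alignment"`: a list with elements
#'   `distance`, `accumulated`, `K` (path length), and `path` (a K x 2
#'   integer matrix of aligned 1-based indices into `x` and `y`).
#' @examples
#' a <- dtw_distance(c(0, 1, 0), c(0, 0, 1, 0))
#' a$distance
#' a$path
#' @export
dtw_distance <- function(x, y, normalize = TRUE, band = NULL) {
  if (length(x) < 1L || length(y) < 1L)
    stop("'x' and 'y' must each contain at least one sample")
  if (anyNA(x) || anyNA(y)) stop("NA values are not allowed in the series")
  r <- .dtw_cpp(as.numeric(x), as.numeric(y), isTRUE(normalize),
                if (is.null(band)) -1L else as.integer(band))
  out <- list(distance = r$distance, accumulated = r$accumulated, K = r$K,
              path = cbind(index_x = r$index_x, index_y = r$index_y),
              normalized = isTRUE(normalize))
  class(out) <- "dtw_alignment"
  out
}

#' @export
print.dtw_alignment <- function(x, ...) {
  cat("DTW alignment: distance =", format(x$distance, digits = 6),
      if (x$normalized) "(accumulated / K)" else "(accumulated)",
      "\n  path length K =", x$K,
      " endpoints (1,1) -> (", max(x$path[, 1]), ",", max(x$path[, 2]),
      ")\n")
  invisible(x)
}

#' @export
plot.dtw_alignment <- function(x, ...) {
  plot(x$path[, 2], x$path[, 1], type = "s",
       xlab = "index into y", ylab = "index into x",
       main = "Optimal warping path", ...)
  invisible(x)
}

#' Pairwise DTW distance matrix for one electrode
#'
#' Computes the realigned (DTW) distance between every pair of trials of
#' one electrode. Trials may have unequal lengths. The result is the
#' per-electrode dissimilarity that the kernel stage turns into a Gaussian
#' similarity.
#'
#' @param epochs an [epoch_set()] (or a plain list of numeric vectors, one
#'   trial each).
#' @param electrode electrode index (ignored when `epochs` is already a
#'   list of single-electrode trial vectors).
#' @param normalize,band see [dtw_distance()].
#' @return an object of class `"distance_matrix"`: a symmetric trial x
#'   trial matrix with zero diagonal, with attributes `electrode` and
#'   `trial_ids`.
#' @export
pairwise_dtw <- function(epochs, electrode = 1L, normalize = TRUE,
                         band = NULL) {
  trials <- .electrode_trials(epochs, electrode)
  if (length(trials) < 2L) stop("need at least 2 trials")
  D <- .dtw_pairwise_cpp(trials, isTRUE(normalize),
                         if (is.null(band)) -1L else as.integer(band))
  .as_distance_matrix(D, electrode, names(trials))
}

#' Fixed-time (no-alignment) Euclidean distance matrix for one electrode
#'
#' The control condition for the alignment step: trials are truncated to
#' the shortest common length and compared sample-by-sample with no
#' warping; the distance is the mean absolute per-sample difference, on
#' the same per-sample scale as the normalized DTW distance.
#'
#' @inheritParams pairwise_dtw
#' @return a `"distance_matrix"` as in [pairwise_dtw()].
#' @export
pairwise_euclidean <- function(epochs, electrode = 1L) {
  trials <- .electrode_trials(epochs, electrode)
  if (length(trials) < 2L) stop("need at least 2 trials")
  len <- min(lengths(trials))
  X <- vapply(trials, function(v) v[seq_len(len)], numeric(len))
  n <- ncol(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- D[j, i] <- mean(abs(X[, i] - X[, j]))
  .as_distance_matrix(D, electrode, names(trials))
}

# pull one electrode's trials out of an epoch_set (row = electrode)
.electrode_trials <- function(epochs, electrode) {
  if (inherits(epochs, "epoch_set")) {
    ne <- nrow(epochs$trials[[1L]])
    if (electrode < 1L || electrode > ne)
      stop("electrode index out of range (1..", ne, ")")
    lapply(epochs$trials, function(m) as.numeric(m[electrode, ]))
  } else if (is.list(epochs)) {
    lapply(epochs, as.numeric)
  } else stop("'epochs' must be an epoch_set or a list of trial vectors")
}

.as_distance_matrix <- function(D, electrode, trial_ids = NULL) {
  structure(D, class = c("distance_matrix", "matrix"),
            electrode = electrode, trial_ids = trial_ids)
}
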