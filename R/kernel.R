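#' Discriminative power index of one electrode
#'
#' Rank AUC of the electrode's realigned (DTW) distances as a score
#' separating between-class trial pairs (label 1) from within-class pairs
#' (label 0), over the strict upper triangle of the distance matrix. It
#' equals the Wilcoxon rank-sum statistic scaled to `[0, 1]` (midranks for
#' ties). Values above 0.5 mean within-class distances tend to be smaller
#' than between-class ones, i.e. the electrode separates the two words;
#' 0.5 is chance. Being a rank statistic, the index is invariant under any
#' strictly monotone transform of the distances.
#'
#' @param D a symmetric trial x trial distance matrix (e.g. from
#'   [pairwise_dtw()]), computed from training trials only.
#' @param labels word label per trial; exactly two classes must be
#'   present.
#' @return the discriminative power index, a number in `[0, 1]`.
#' @export
discriminative_power_index <- function(D, labels) {
  D <- unclass(as.matrix(D))
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) != 2L)
    stop("exactly two classes must be present")
  n <- nrow(D)
  if (length(labels) != n) stop("'labels' must match the matrix dimension")
  ut <- upper.tri(D)
  d <- D[ut]
  between <- outer(labels, labels, "!=")[ut]
  n1 <- sum(between)
  n0 <- sum(!between)
  if (n1 == 0L || n0 == 0L) stop("need both within- and between-class pairs")
  r <- rank(d)
  (sum(r[between]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Normalized electrode weights from discriminative power
#'
#' Fixed-rule multiple-kernel weights: each electrode's weight is its
#' discriminative power index divided by the sum over electrodes, so the
#' weights are nonnegative and sum to one. With `floor_chance = TRUE`,
#' `max(dpi - 0.5, 0)` is normalized instead, zeroing out chance-level
#' electrodes (uniform weights are returned if every electrode is at or
#' below chance).
#'
#' @param dpi numeric vector of per-electrode indices in `[0, 1]`.
#' @param floor_chance subtract the 0.5 chance level (and floor at 0)
#'   before normalizing?
#' @return an object of class `"electrode_weights"`: a list with `dpi` and
#'   `w_hat` (the normalized weights).
#' @export
kernel_weights <- function(dpi, floor_chance = FALSE) {
  if (any(dpi < 0 | dpi > 1)) stop("'dpi' values must lie in [0, 1]")
  w <- if (floor_chance) pmax(dpi - 0.5, 0) else dpi
  w_hat <- if (sum(w) > 0) w / sum(w) else rep(1 / length(w), length(w))
  structure(list(dpi = dpi, w_hat = w_hat), class = "electrode_weights")
}

#' @export
print.electrode_weights <- function(x, ...) {
  cat("Electrode weights (fixed-rule MKL):\n")
  print(round(rbind(dpi = x$dpi, w_hat = x$w_hat), 4))
  invisible(x)
}

#' Gaussian kernel of one electrode's distance matrix
#'
#' Entry (i, j) is `exp(-gamma * D[i, j])`: similarity 1 on the diagonal,
#' strictly decreasing in the realigned distance.
#'
#' @param D a trial x trial distance matrix.
#' @param gamma kernel bandwidth, > 0.
#' @return a symmetric kernel matrix with unit diagonal and entries in
#'   `(0, 1]`.
#' @export
electrode_kernel <- function(D, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("'gamma' must be a single value > 0")
  K <- exp(-gamma * unclass(as.matrix(D)))
  structure(K, class = c("kernel_matrix", "matrix"), gamma = gamma)
}

#' Combine per-electrode kernels by weighted sum
#'
#' Fixed-rule multiple kernel learning: the combined trial similarity is
#' `K = sum_e w_hat_e * K_e` with the normalized discriminative-power
#' weights. With weights summing to one the combined kernel keeps a unit
#' diagonal and entries in `(0, 1]`. Positive semidefiniteness is not
#' guaranteed (Gaussians of DTW distances are indefinite in general); the
#' smallest eigenvalue is recorded in attribute `"min_eigenvalue"`, not
#' enforced.
#'
#' @param kernels list of per-electrode kernel matrices on the same trial
#'   set.
#' @param weights an [kernel_weights()] object (or a numeric vector of
#'   normalized weights).
#' @return a combined `"kernel_matrix"`.
#' @export
combine_kernels <- function(kernels, weights) {
  w <- if (inherits(weights, "electrode_weights")) weights$w_hat
       else as.numeric(weights)
  if (length(kernels) != length(w))
    stop("need one weight per kernel")
  dims <- vapply(kernels, function(k) dim(as.matrix(k)), integer(2))
  if (any(dims != dims[, 1L]))
    stop("all kernels must share the same trial set (dimension mismatch)")
  K <- Reduce(`+`, Map(function(k, wi) wi * unclass(as.matrix(k)),
                       kernels, w))
  ev <- tryCatch(min(eigen(K, symmetric = TRUE,
                           only.values = TRUE)$values),
                 error = function(e) NA_real_)
  structure(K, class = c("kernel_matrix", "matrix"),
            weights = w, min_eigenvalue = ev)
}

#' Combined kernel rows between held-out and training trials
#'
#' Evaluates the decoder's similarity between new (test) trials and the
#' training trials: entry (t, i) is
#' `sum_e w_hat_e * exp(-gamma * d_e(test_t, train_i))`, with the
#' per-electrode distances computed by DTW (or fixed-time Euclidean when
#' `align = FALSE`) using weights and bandwidth fixed from training. A
#' test trial identical to a training trial reproduces that trial's
#' training-kernel row.
#'
#' @param train_epochs,test_epochs [epoch_set()]s sharing the electrode
#'   count and order.
#' @param weights an [kernel_weights()] object fixed on the training set.
#' @param gamma kernel bandwidth fixed on the training set.
#' @param align use DTW alignment (`TRUE`) or fixed-time Euclidean
#'   distances on the shortest common length (`FALSE`)?
#' @param band optional Sakoe-Chiba band, see [dtw_distance()].
#' @return a test x train matrix of combined kernel values.
#' @export
cross_kernel <- function(train_epochs, test_epochs, weights, gamma,
                         align = TRUE, band = NULL) {
  stopifnot(inherits(train_epochs, "epoch_set"),
            inherits(test_epochs, "epoch_set"))
  ne <- nrow(train_epochs$trials[[1L]])
  if (nrow(test_epochs$trials[[1L]]) != ne)
    stop("electrode mismatch between training and test epochs")
  w <- if (inherits(weights, "electrode_weights")) weights$w_hat
       else as.numeric(weights)
  if (length(w) != ne) stop("need one weight per electrode")
  if (gamma <= 0) stop("'gamma' must be > 0")
  nt <- length(test_epochs$trials)
  nr <- length(train_epochs$trials)
  K <- matrix(0, nt, nr)
  for (e in seq_len(ne)) {
    tr <- lapply(train_epochs$trials, function(m) as.numeric(m[e, ]))
    te <- lapply(test_epochs$trials, function(m) as.numeric(m[e, ]))
    Dte <- if (align) {
      .dtw_cross_cpp(te, tr, TRUE, if (is.null(band)) -1L
                     else as.integer(band))
    } else {
      len <- min(min(lengths(tr)), min(lengths(te)))
      A <- vapply(te, function(v) v[seq_len(len)], numeric(len))
      B <- vapply(tr, function(v) v[seq_len(len)], numeric(len))
      Dm <- matrix(0, nt, nr)
      for (i in seq_len(nt)) for (j in seq_len(nr))
        Dm[i, j] <- mean(abs(A[, i] - B[, j]))
      Dm
    }
    K <- K + w[e] * exp(-gamma * Dte)
  }
  K
}
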