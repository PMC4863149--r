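# shared plumbing: per-electrode pairwise distances for an epoch set
.all_distances <- function(epochs, align = TRUE, band = NULL) {
  ne <- nrow(epochs$trials[[1L]])
  lapply(seq_len(ne), function(e)
    if (align) pairwise_dtw(epochs, e, band = band)
    else pairwise_euclidean(epochs, e))
}

# default bandwidth grid: gamma = 2^(-4..2) / median off-diagonal training
# distance (pooled over electrodes)
.default_gamma_grid <- function(dist_list, idx = NULL) {
  offd <- unlist(lapply(dist_list, function(D) {
    D <- unclass(as.matrix(D))
    if (!is.null(idx)) D <- D[idx, idx, drop = FALSE]
    D[upper.tri(D)]
  }))
  med <- median(offd)
  if (!is.finite(med) || med <= 0) med <- 1
  2^(-4:2) / med
}

# one-per-class fold ids: within each class trials get fold 1..n_c; ids
# beyond the smaller class count are 0 (always in training, never tested)
.pair_folds <- function(labels) {
  labels <- factor(labels)
  folds <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    folds[idx] <- seq_along(idx)
  }
  nf <- min(tabulate(labels))
  folds[folds > nf] <- 0L
  list(folds = folds, n_folds = nf)
}

#' Fit the DTW-kernel multiple-kernel SVM decoder
#'
#' The package's core model: per-electrode trial distances (DTW-realigned
#' by default), electrode weights from the discriminative power index,
#' Gaussian kernels combined by fixed-rule multiple kernel learning, and
#' a soft-margin SVM on the combined precomputed kernel.
#'
#' @param epochs an [epoch_set()] with exactly two word labels.
#' @param gamma kernel bandwidth; default `1 / median` off-diagonal
#'   training distance.
#' @param C soft-margin parameter.
#' @param align DTW alignment (`TRUE`) or fixed-time Euclidean control
#'   (`FALSE`).
#' @param floor_chance see [kernel_weights()].
#' @param band optional Sakoe-Chiba band, see [dtw_distance()].
#' @param distances optional precomputed list of per-electrode distance
#'   matrices (as produced by [pairwise_dtw()]), to avoid recomputation.
#' @return an object of class `"word_decoder"` with `print`, `coef` and
#'   `predict` methods. `coef` returns the electrode weights; `predict`
#'   takes a new `epoch_set` and returns word labels.
#' @examples
#' cfg <- synth_config(n_trials_per_class = 5, n_electrodes = 3,
#'                     n_informative = 3, noise_sd = 0.3, seed = 7)
#' es <- generate_epochs(cfg)
#' fit <- fit_decoder(es)
#' fit
#' table(predict(fit, es), es$labels)
#' @export
fit_decoder <- function(epochs, gamma = NULL, C = 1, align = TRUE,
                        floor_chance = FALSE, band = NULL,
                        distances = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (nlevels(droplevels(epochs$labels)) != 2L)
    stop("the decoder is pairwise: exactly two word labels are required")
  if (is.null(distances)) distances <- .all_distances(epochs, align, band)
  if (is.null(gamma)) gamma <- .default_gamma_grid(distances)[5L]  # 1/med
  dpi <- vapply(distances, discriminative_power_index, numeric(1),
                labels = epochs$labels)
  w <- kernel_weights(dpi, floor_chance = floor_chance)
  K <- combine_kernels(lapply(distances, electrode_kernel, gamma = gamma),
                       w)
  svm <- train_svm(K, epochs$labels, C = C)
  structure(list(svm = svm, weights = w, gamma = gamma, C = C,
                 align = align, band = band, train_epochs = epochs,
                 kernel = K),
            class = "word_decoder")
}

#' @export
print.word_decoder <- function(x, ...) {
  cat("DTW-MKL-SVM word decoder (", if (x$align) "DTW alignment"
      else "no alignment", ")\n", sep = "")
  cat("  words:", paste(x$svm$levels, collapse = " vs "),
      " trials:", x$svm$n, "\n")
  cat("  gamma =", format(x$gamma, digits = 4), " C =", x$C,
      " support vectors:", sum(x$svm$alpha > 1e-10), "\n")
  cat("  electrode weights:",
      paste(round(x$weights$w_hat, 3), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.word_decoder <- function(object, ...) object$weights

#' Predict word labels for new trials
#'
#' @param object a [fit_decoder()] fit.
#' @param newdata an [epoch_set()] with the same electrodes.
#' @param type `"class"` for labels, `"decision"` for decision values.
#' @param ... unused.
#' @export
predict.word_decoder <- function(object, newdata,
                                 type = c("class", "decision"), ...) {
  type <- match.arg(type)
  rows <- cross_kernel(object$train_epochs, newdata, object$weights,
                       object$gamma, align = object$align,
                       band = object$band)
  if (type == "decision") decision_values(object$svm, rows)
  else predict(object$svm, rows)
}

#' Nested leave-one-out cross-validation of the decoder
#'
#' The evaluation protocol: outer folds each hold out one trial per class
#' (fold count = the smaller class count). Within each outer training set,
#' per-electrode distances, discriminative-power weights and the
#' `(gamma, C)` grid search (by an inner leave-one-out with the same
#' one-per-class fold structure) are computed from training trials only;
#' the model is then refit on the full training set and evaluated on the
#' held-out pair. No held-out information enters the distance, weight or
#' grid-search computation. Accuracy is the fraction of held-out trials
#' classified correctly.
#'
#' Grid-selection ties are broken toward the smallest `C`, then the
#' smallest `gamma` (preferring smoother models). Trial-pair distances do
#' not depend on labels, so the full pairwise distance matrices are
#' computed once and subset per fold — identical to per-fold recomputation
#' and leakage-free.
#'
#' @param epochs an [epoch_set()].
#' @param word_pair optional character vector of two words to decode
#'   (defaults to the two labels present); each needs >= 3 trials.
#' @param gamma_grid bandwidth grid; default `2^(-4:2)` divided by the
#'   median off-diagonal training distance of each outer fold.
#' @param C_grid soft-margin grid (default `10^(-2:2)`).
#' @param align,floor_chance,band,distances see [fit_decoder()].
#' @param labels optional label override (used by the permutation test).
#' @return an object of class `"decode_cv"`: `accuracy`, a `folds`
#'   data.frame (held-out trial, truth, prediction, selected gamma and C),
#'   and the per-fold electrode weights.
#' @export
nested_loocv <- function(epochs, word_pair = NULL, gamma_grid = NULL,
                         C_grid = c(0.01, 0.1, 1, 10, 100), align = TRUE,
                         floor_chance = FALSE, band = NULL,
                         distances = NULL, labels = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (length(C_grid) < 1L) stop("'C_grid' must not be empty")
  if (!is.null(gamma_grid) && length(gamma_grid) < 1L)
    stop("'gamma_grid' must not be empty")
  lab <- if (is.null(labels)) epochs$labels else factor(labels)
  if (is.null(word_pair)) {
    word_pair <- levels(droplevels(lab))
    if (length(word_pair) != 2L)
      stop("specify 'word_pair': data contain ", length(word_pair),
           " words")
  }
  keep <- which(lab %in% word_pair)
  lab <- droplevels(factor(lab[keep], levels = sort(word_pair)))
  if (any(tabulate(lab) < 3L))
    stop("each word of the pair needs at least 3 trials")
  if (is.null(distances)) {
    distances <- .all_distances(epochs[keep], align, band)
  } else {
    distances <- lapply(distances, function(D)
      unclass(as.matrix(D))[keep, keep, drop = FALSE])
  }
  n <- length(keep)
  t_sign <- ifelse(as.character(lab) == levels(lab)[1L], 1, -1)
  pf <- .pair_folds(lab)
  C_grid <- sort(C_grid)
  user_gamma <- !is.null(gamma_grid)
  if (user_gamma) gamma_grid <- sort(gamma_grid)

  pred <- character(n)
  sel_gamma <- sel_C <- rep(NA_real_, pf$n_folds)
  w_folds <- matrix(NA_real_, pf$n_folds, length(distances))
  for (f in seq_len(pf$n_folds)) {
    te <- which(pf$folds == f)
    tr <- setdiff(seq_len(n), te)
    Dtr <- lapply(distances, function(D) D[tr, tr, drop = FALSE])
    dpi <- vapply(Dtr, discriminative_power_index, numeric(1),
                  labels = lab[tr])
    w <- kernel_weights(dpi, floor_chance = floor_chance)
    gg <- if (user_gamma) gamma_grid else .default_gamma_grid(Dtr)
    inner <- .pair_folds(lab[tr])
    acc <- matrix(NA_real_, length(gg), length(C_grid))
    Ktr_list <- vector("list", length(gg))
    for (gi in seq_along(gg)) {
      Ktr <- Reduce(`+`, Map(function(D, wi) wi * exp(-gg[gi] * D),
                             Dtr, w$w_hat))
      Ktr_list[[gi]] <- Ktr
      acc[gi, ] <- .loocv_grid_cpp(Ktr, t_sign[tr], inner$folds, C_grid)
    }
    # best inner accuracy; ties -> smallest C, then smallest gamma
    best <- c(1L, 1L)
    for (ci in seq_along(C_grid)) for (gi in seq_along(gg))
      if (acc[gi, ci] > acc[best[1L], best[2L]] + 1e-12)
        best <- c(gi, ci)
    sel_gamma[f] <- gg[best[1L]]
    sel_C[f] <- C_grid[best[2L]]
    w_folds[f, ] <- w$w_hat
    svm <- train_svm(Ktr_list[[best[1L]]], lab[tr], C = sel_C[f])
    rows <- Reduce(`+`, Map(function(D, wi)
      wi * exp(-sel_gamma[f] * D[te, tr, drop = FALSE]),
      distances, w$w_hat))
    pred[te] <- as.character(predict(svm, rows))
  }
  tested <- pf$folds > 0L
  folds_df <- data.frame(fold = pf$folds[tested],
                         trial = which(tested),
                         truth = as.character(lab)[tested],
                         pred = pred[tested],
                         stringsAsFactors = FALSE)
  folds_df <- folds_df[order(folds_df$fold, folds_df$truth), ]
  folds_df$gamma <- sel_gamma[folds_df$fold]
  folds_df$C <- sel_C[folds_df$fold]
  structure(list(accuracy = mean(folds_df$pred == folds_df$truth),
                 folds = folds_df, n_folds = pf$n_folds,
                 word_pair = levels(lab), align = align,
                 weights = w_folds, C_grid = C_grid,
                 gamma_grid = if (user_gamma) gamma_grid else NULL),
            class = "decode_cv")
}

#' @export
print.decode_cv <- function(x, ...) {
  cat("Nested LOOCV decoding: ", paste(x$word_pair, collapse = " vs "),
      " (", if (x$align) "DTW alignment" else "no alignment", ")\n",
      sep = "")
  cat("  accuracy = ", sprintf("%.1f%%", 100 * x$accuracy), " over ",
      x$n_folds, " outer folds (", nrow(x$folds), " held-out trials)\n",
      sep = "")
  cat("  selected C: ", paste(unique(x$folds$C), collapse = ", "),
      "; gamma range: ",
      paste(format(range(x$folds$gamma), digits = 3), collapse = " - "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.decode_cv <- function(object, ...) {
  cat("Per-fold predictions:\n")
  print(object$folds, row.names = FALSE)
  cat("\nMean electrode weights across folds:\n")
  print(round(colMeans(object$weights), 4))
  invisible(object)
}
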