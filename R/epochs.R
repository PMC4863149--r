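#' Construct an epoch set
#'
#' An epoch set holds the single-trial feature data consumed by the
#' decoder: one electrodes x time matrix per trial (trial lengths may
#' differ, e.g. speech-onset/offset-bounded epochs), a word label per
#' trial, the feature sampling rate, and the task condition.
#'
#' @param trials list of numeric matrices, each electrodes x time; all
#'   trials must share the electrode count (and ordering).
#' @param labels character or factor of word labels, one per trial.
#' @param fs_feat feature sampling rate in samples/s (typically 100, the
#'   post-decimation high-gamma rate).
#' @param condition one of `"listening"`, `"overt"`, `"imagined"`, or
#'   `"synthetic"`.
#' @return an object of class `"epoch_set"`.
#' @export
epoch_set <- function(trials, labels, fs_feat = 100,
                      condition = "synthetic") {
  if (!is.list(trials) || length(trials) < 1L)
    stop("'trials' must be a non-empty list of electrode x time matrices")
  trials <- lapply(trials, function(m) {
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
    as.matrix(m)
  })
  ne <- vapply(trials, nrow, integer(1))
  if (length(unique(ne)) != 1L)
    stop("all trials must have the same electrode count")
  if (length(labels) != length(trials))
    stop("'labels' must have one entry per trial")
  if (!is.numeric(fs_feat) || fs_feat <= 0) stop("'fs_feat' must be > 0")
  structure(list(trials = trials, labels = factor(labels),
                 fs_feat = fs_feat, condition = condition),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  len <- vapply(x$trials, ncol, integer(1))
  cat("Epoch set (", x$condition, "): ", length(x$trials), " trials, ",
      nrow(x$trials[[1L]]), " electrodes, fs ", x$fs_feat, " Hz\n",
      sep = "")
  cat("  labels: ", paste(sprintf("%s (%d)", levels(x$labels),
                                  tabulate(x$labels)), collapse = ", "),
      "\n  trial length: ", min(len), "-", max(len), " samples\n", sep = "")
  invisible(x)
}

#' Number of trials in an epoch set
#' @param x an `epoch_set`.
#' @export
length.epoch_set <- function(x) length(x$trials)

#' Plot per-class mean time courses of one electrode
#'
#' Overlays the across-trial mean feature time course of each word for a
#' chosen electrode (trials truncated to the shortest length).
#'
#' @param x an `epoch_set`.
#' @param electrode electrode index.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.epoch_set <- function(x, electrode = 1L, ...) {
  len <- min(vapply(x$trials, ncol, integer(1)))
  tt <- (seq_len(len) - 1) / x$fs_feat
  avg <- vapply(levels(x$labels), function(lv) {
    idx <- which(x$labels == lv)
    rowMeans(vapply(x$trials[idx],
                    function(m) m[electrode, seq_len(len)], numeric(len)))
  }, numeric(len))
  matplot(tt, avg, type = "l", lty = 1, lwd = 2,
          xlab = "time (s)", ylab = "high-gamma (z)",
          main = paste("Electrode", electrode), ...)
  legend("topright", legend = levels(x$labels), col = seq_len(ncol(avg)),
         lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

#' Subset an epoch set by trial index
#' @param x an `epoch_set`.
#' @param i trial indices.
#' @export
`[.epoch_set` <- function(x, i) {
  epoch_set(x$trials[i], x$labels[i], x$fs_feat, x$condition)
}
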