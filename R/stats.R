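#' Full-pipeline label-permutation significance test
#'
#' Builds the empirical null of decoding accuracy by shuffling the trial
#' labels and rerunning the entire nested leave-one-out pipeline for each
#' shuffle: discriminative-power weighting, bandwidth/C grid search, SVM
#' fitting and outer-fold evaluation are all recomputed under the permuted
#' labels. Trial-pair distances are label-free and therefore reused across
#' permutations (identical to recomputation). The p-value uses the add-one
#' convention `p = (#\{null >= observed\} + 1) / (n_perm + 1)`, so it is
#' never exactly zero; `add_one = FALSE` gives the plain proportion. For a
#' balanced two-class design the null is centred near 50% accuracy.
#'
#' @param epochs an [epoch_set()].
#' @param word_pair,gamma_grid,C_grid,align,floor_chance,band see
#'   [nested_loocv()].
#' @param n_perm number of label shuffles (>= 1). Default 200; increase
#'   (the reference protocol used 1000) for finer p-value resolution.
#' @param seed integer seed for the shuffle stream; the global RNG state
#'   is saved and restored, so the null is reproducible and isolated.
#' @return an object of class `"perm_test"`: `observed` accuracy,
#'   `perm_accuracies`, `p_value`, `n_perm`.
#' @export
permutation_test <- function(epochs, word_pair = NULL, n_perm = 200,
                             seed = NULL, gamma_grid = NULL,
                             C_grid = c(0.01, 0.1, 1, 10, 100),
                             align = TRUE, floor_chance = FALSE,
                             band = NULL, add_one = TRUE) {
  if (!is.numeric(n_perm) || n_perm < 1) stop("'n_perm' must be >= 1")
  stopifnot(inherits(epochs, "epoch_set"))
  lab <- epochs$labels
  if (is.null(word_pair)) word_pair <- levels(droplevels(lab))
  keep <- which(lab %in% word_pair)
  sub <- epochs[keep]
  distances <- .all_distances(sub, align, band)
  run <- function(lbl) nested_loocv(sub, word_pair = word_pair,
                                    gamma_grid = gamma_grid,
                                    C_grid = C_grid, align = align,
                                    floor_chance = floor_chance,
                                    band = band, distances = distances,
                                    labels = lbl)$accuracy
  observed <- run(NULL)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  null_acc <- vapply(seq_len(n_perm),
                     function(b) run(sample(sub$labels)), numeric(1))
  hits <- sum(null_acc >= observed)   # ">=": conservative null count
  p <- if (add_one) (hits + 1) / (n_perm + 1) else hits / n_perm
  structure(list(observed = observed, perm_accuracies = null_acc,
                 p_value = p, n_perm = as.integer(n_perm),
                 word_pair = word_pair, add_one = add_one),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test (", x$n_perm, " label shuffles, full pipeline)\n",
      sep = "")
  cat("  ", paste(x$word_pair, collapse = " vs "), ": observed accuracy ",
      sprintf("%.1f%%", 100 * x$observed), "\n", sep = "")
  cat("  null mean ", sprintf("%.1f%%", 100 * mean(x$perm_accuracies)),
      ", p = ", format(x$p_value, digits = 4),
      if (x$add_one) " (add-one convention)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
plot.perm_test <- function(x, ...) {
  hist(100 * x$perm_accuracies, breaks = 20,
       main = "Permutation null of decoding accuracy",
       xlab = "accuracy (%)", ...)
  abline(v = 100 * x$observed, col = "red", lwd = 2)
  legend("topright", legend = sprintf("observed (p = %.3g)", x$p_value),
         col = "red", lwd = 2, bty = "n")
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Wraps `stats::p.adjust(method = "BH")` and applies the step-up
#' rejection rule at level `alpha`.
#'
#' @param p_values numeric vector of p-values in `(0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return a list with `reject` (logical), `p_adjusted`, and `alpha`.
#' @export
fdr_correct <- function(p_values, alpha = 0.05) {
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  adj <- p.adjust(p_values, method = "BH")
  list(reject = adj <= alpha, p_adjusted = adj, alpha = alpha)
}

#' One-sample t-test of decoding accuracies against chance
#'
#' Tests whether the mean of a set of accuracies differs from the 50%
#' two-class chance level (two-sided by default). With zero variance at
#' exactly the chance level the test is degenerate; `t = 0`, `p = 1` is
#' returned with a warning.
#'
#' @param accuracies numeric vector of accuracies in `[0, 1]` (>= 2
#'   values).
#' @param chance chance level (default 0.5).
#' @param alternative passed to [stats::t.test()].
#' @return a list with `t`, `p_value`, `mean`, `n`.
#' @export
ttest_vs_chance <- function(accuracies, chance = 0.5,
                            alternative = "two.sided") {
  if (length(accuracies) < 2L) stop("need at least 2 accuracy values")
  if (sd(accuracies) == 0) {
    if (isTRUE(all.equal(mean(accuracies), chance))) {
      warning("zero variance at chance level: returning t = 0, p = 1")
      return(list(t = 0, p_value = 1, mean = mean(accuracies),
                  n = length(accuracies)))
    }
    warning("zero variance away from chance: test degenerate, p = 0")
    return(list(t = sign(mean(accuracies) - chance) * Inf, p_value = 0,
                mean = mean(accuracies), n = length(accuracies)))
  }
  tt <- t.test(accuracies, mu = chance, alternative = alternative)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean = mean(accuracies), n = length(accuracies))
}
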