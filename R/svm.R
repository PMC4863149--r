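#' Train a soft-margin SVM on a precomputed kernel
#'
#' Solves the soft-margin dual on the supplied (possibly indefinite)
#' trial x trial kernel by sequential minimal optimization with
#' maximal-violating-pair working-set selection. Labels are mapped to
#' signs deterministically: the lexicographically first word is +1. The
#' decision value of a trial with kernel row `k` is
#' `sum_i alpha_i t_i k_i + beta0`; a decision value of exactly zero is
#' classified +1.
#'
#' @param K_train square kernel matrix over the training trials.
#' @param labels word label per training trial; exactly two classes.
#' @param C soft-margin parameter (> 0): trade-off between training error
#'   and decision-boundary smoothness.
#' @param eps duality-gap convergence tolerance.
#' @return an object of class `"kernel_svm"` with elements `alpha` (in
#'   `[0, C]`), `t` (signs), `beta0`, `C`, `levels` (word for +1 first),
#'   and `iterations`.
#' @export
train_svm <- function(K_train, labels, C = 1, eps = 1e-6) {
  K_train <- unclass(as.matrix(K_train))
  if (nrow(K_train) != ncol(K_train)) stop("'K_train' must be square")
  labels <- factor(labels)
  lev <- sort(levels(droplevels(labels)))
  if (length(lev) != 2L)
    stop("exactly two classes are required (got ",
         length(lev), ")")
  if (length(labels) != nrow(K_train))
    stop("'labels' must have one entry per training trial")
  if (!is.numeric(C) || C <= 0) stop("'C' must be > 0")
  t_sign <- ifelse(as.character(labels) == lev[1L], 1, -1)
  fit <- .smo_cpp(K_train, t_sign, C, eps)
  structure(list(alpha = fit$alpha, t = t_sign, beta0 = fit$b, C = C,
                 levels = lev, iterations = fit$iterations,
                 n = nrow(K_train)),
            class = "kernel_svm")
}

#' @export
print.kernel_svm <- function(x, ...) {
  cat("Precomputed-kernel SVM: n =", x$n, " C =", x$C,
      "\n  support vectors:", sum(x$alpha > 1e-10),
      " beta0 =", format(x$beta0, digits = 5),
      "\n  +1 class:", x$levels[1L], " -1 class:", x$levels[2L], "\n")
  invisible(x)
}

#' Decision values for kernel rows
#'
#' @param model a [train_svm()] fit.
#' @param cross_rows test x train matrix of combined kernel values (e.g.
#'   from [cross_kernel()]).
#' @return numeric decision values, one per test row.
#' @export
decision_values <- function(model, cross_rows) {
  stopifnot(inherits(model, "kernel_svm"))
  cross_rows <- matrix(as.numeric(cross_rows), ncol = model$n)
  as.numeric(cross_rows %*% (model$alpha * model$t)) + model$beta0
}

#' Predict word labels from kernel rows
#'
#' @param object a [train_svm()] fit.
#' @param cross_rows test x train kernel rows computed with the model's
#'   weights and bandwidth.
#' @param ... unused.
#' @return factor of predicted word labels (ties at decision value 0 go
#'   to the +1 class).
#' @export
predict.kernel_svm <- function(object, cross_rows, ...) {
  if (NCOL(cross_rows) != object$n)
    stop("kernel row length (", NCOL(cross_rows),
         ") does not match training size (", object$n, ")")
  dv <- decision_values(object, cross_rows)
  factor(ifelse(dv >= 0, object$levels[1L], object$levels[2L]),
         levels = object$levels)
}
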