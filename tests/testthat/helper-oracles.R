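# Independent oracles used by the unit and acceptance tests. These
# deliberately avoid the package's dynamic-programming / rank-statistic
# code paths.

# every admissible warping path from (1,1) to (M,N) with steps
# {(1,0),(0,1),(1,1)}, as a list of K x 2 index matrices
enumerate_paths <- function(M, N) {
  if (M == 1 && N == 1) return(list(matrix(c(1, 1), ncol = 2)))
  out <- list()
  grow <- function(prefix) {
    m <- prefix[nrow(prefix), 1]
    n <- prefix[nrow(prefix), 2]
    if (m == M && n == N) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    if (m < M && n < N) grow(rbind(prefix, c(m + 1, n + 1)))
    if (m < M) grow(rbind(prefix, c(m + 1, n)))
    if (n < N) grow(rbind(prefix, c(m, n + 1)))
  }
  grow(matrix(c(1, 1), ncol = 2))
  out
}

# brute-force minimal accumulated distortion over all admissible paths
brute_force_dtw <- function(x, y) {
  paths <- enumerate_paths(length(x), length(y))
  acc <- vapply(paths, function(p)
    sum(abs(x[p[, 1]] - y[p[, 2]])), numeric(1))
  k <- lengths(lapply(paths, function(p) p[, 1]))
  list(min_acc = min(acc),
       norm_candidates = acc[acc <= min(acc) + 1e-12] /
         k[acc <= min(acc) + 1e-12])
}

# AUC by explicit pair counting (ties count 1/2)
pair_count_auc <- function(scores_pos, scores_neg) {
  gt <- outer(scores_pos, scores_neg, ">")
  eq <- outer(scores_pos, scores_neg, "==")
  (sum(gt) + 0.5 * sum(eq)) / (length(scores_pos) * length(scores_neg))
}

# a small separable two-class epoch set used across tests
make_toy_epochs <- function(n_per_class = 5, noise_sd = 0.3,
                            n_electrodes = 3, n_informative = 3,
                            seed = 42, ...) {
  cfg <- synth_config(n_trials_per_class = n_per_class,
                      n_electrodes = n_electrodes,
                      n_informative = n_informative,
                      noise_sd = noise_sd, seed = seed, ...)
  generate_epochs(cfg)
}

# paired t-test p-value that tolerates an all-zero difference vector
safe_paired_p <- function(a, b, alternative = "two.sided") {
  d <- a - b
  if (sd(d) == 0) return(if (mean(d) == 0) 1 else 0)
  t.test(a, b, paired = TRUE, alternative = alternative)$p.value
}
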