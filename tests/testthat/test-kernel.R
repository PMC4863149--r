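test_that("DPI is 1 under perfect separation and matches pair counting", {
  labels <- c("a", "a", "b", "b")
  # within-class distances small, between-class large
  D <- matrix(c(0, 1, 9, 8,
                1, 0, 7, 9,
                9, 7, 0, 2,
                8, 9, 2, 0), 4, 4)
  expect_equal(discriminative_power_index(D, labels), 1.0)
  # one inversion: a within distance larger than one between distance
  D2 <- D
  D2[1, 2] <- D2[2, 1] <- 7.5
  ut <- upper.tri(D2)
  between <- outer(labels, labels, "!=")[ut]
  oracle <- pair_count_auc(D2[ut][between], D2[ut][!between])
  expect_equal(discriminative_power_index(D2, labels), oracle)
  expect_lt(discriminative_power_index(D2, labels), 1.0)
  expect_error(discriminative_power_index(D, rep("a", 4)), "two classes")
})

test_that("DPI matches the pair-counting oracle on random instances", {
  set.seed(9)
  for (rep in 1:25) {
    n <- sample(5:9, 1)
    labels <- sample(rep(c("x", "y"), length.out = n))
    M <- matrix(runif(n * n), n)
    D <- M + t(M); diag(D) <- 0
    ut <- upper.tri(D)
    between <- outer(labels, labels, "!=")[ut]
    oracle <- pair_count_auc(D[ut][between], D[ut][!between])
    expect_equal(discriminative_power_index(D, labels), oracle)
    # rank statistic: invariant under strictly monotone transforms
    expect_equal(discriminative_power_index(log1p(D) * 3, labels), oracle)
  }
})

test_that("chance-level distances give DPI near 0.5 on average", {
  set.seed(14)
  labels <- rep(c("a", "b"), each = 6)
  dpis <- vapply(1:200, function(i) {
    M <- matrix(runif(144), 12)
    D <- M + t(M); diag(D) <- 0
    discriminative_power_index(D, labels)
  }, numeric(1))
  expect_lt(abs(mean(dpis) - 0.5), 0.02)
})

test_that("electrode kernels are Gaussian in the distance", {
  D <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(unclass(electrode_kernel(D, 0.5)),
               matrix(c(1, exp(-0.5), exp(-0.5), 1), 2),
               ignore_attr = TRUE)
  expect_equal(unclass(electrode_kernel(matrix(0, 3, 3), 2)),
               matrix(1, 3, 3), ignore_attr = TRUE)
  # doubling gamma squares each entry
  set.seed(1)
  M <- matrix(runif(16), 4); Dr <- M + t(M); diag(Dr) <- 0
  expect_equal(unclass(electrode_kernel(Dr, 2)),
               unclass(electrode_kernel(Dr, 1))^2, ignore_attr = TRUE)
  expect_error(electrode_kernel(D, 0), "gamma")
  expect_error(electrode_kernel(D, -1), "gamma")
})

test_that("weights normalize to one and floor_chance zeroes weak sites", {
  w <- kernel_weights(c(0.9, 0.5, 0.6))
  expect_equal(sum(w$w_hat), 1, tolerance = 1e-12)
  expect_true(all(w$w_hat >= 0))
  expect_equal(w$w_hat, c(0.9, 0.5, 0.6) / 2)
  wf <- kernel_weights(c(0.9, 0.5, 0.45), floor_chance = TRUE)
  expect_equal(wf$w_hat, c(0.4, 0, 0) / 0.4)
  # all at/below chance: uniform fallback
  expect_equal(kernel_weights(c(0.4, 0.5), floor_chance = TRUE)$w_hat,
               c(0.5, 0.5))
  expect_error(kernel_weights(c(1.2, 0.3)), "\\[0, 1\\]")
})

test_that("combining kernels is a convex mix with unit diagonal", {
  set.seed(7)
  mk <- function() {
    M <- matrix(runif(25), 5); D <- M + t(M); diag(D) <- 0
    electrode_kernel(D, 1)
  }
  k1 <- mk(); k2 <- mk()
  expect_equal(unclass(combine_kernels(list(k1), 1)), unclass(k1),
               ignore_attr = TRUE)
  expect_equal(unclass(combine_kernels(list(k1, k1), c(0.5, 0.5))),
               unclass(k1), ignore_attr = TRUE)
  K <- combine_kernels(list(k1, k2), kernel_weights(c(0.7, 0.6)))
  expect_equal(diag(K), rep(1, 5))
  expect_true(all(K > 0 & K <= 1 + 1e-15))
  expect_equal(unclass(K), t(unclass(K)))
  expect_true(is.finite(attr(K, "min_eigenvalue")))
  expect_error(combine_kernels(list(k1, mk()[1:4, 1:4]), c(0.5, 0.5)),
               "dimension|weight")
})

test_that("cross-kernel rows reproduce training columns for copied trials", {
  es <- make_toy_epochs(n_per_class = 4, noise_sd = 0.4)
  dists <- lapply(1:3, function(e) pairwise_dtw(es, e))
  dpi <- vapply(dists, discriminative_power_index, numeric(1),
                labels = es$labels)
  w <- kernel_weights(dpi)
  gamma <- 0.8
  K <- combine_kernels(lapply(dists, electrode_kernel, gamma = gamma), w)
  rows <- cross_kernel(es, es[c(3, 6)], w, gamma)
  expect_equal(rows[1, ], unclass(K)[, 3], tolerance = 1e-12)
  expect_equal(rows[2, ], unclass(K)[, 6], tolerance = 1e-12)
  # distant test trial: all similarities decay to ~0
  far <- es[1]
  far$trials[[1]] <- far$trials[[1]] + 1e4
  expect_lt(max(cross_kernel(es, far, w, gamma)), 1e-10)
  # electrode mismatch is refused
  bad <- epoch_set(list(matrix(rnorm(20), 2)), "spoon")
  expect_error(cross_kernel(es, bad, w, gamma), "electrode mismatch")
})

test_that("a hand-computed 3-train/1-test cross-kernel row checks out", {
  # two electrodes with hand-set distances from the test trial to the
  # three training trials; weights (0.25, 0.75), gamma = 0.5
  d1 <- c(0, 1, 2)
  d2 <- c(4, 0, 1)
  expected <- 0.25 * exp(-0.5 * d1) + 0.75 * exp(-0.5 * d2)
  # build trials realising those distances on constant series (DTW distance
  # between constant series is the absolute offset)
  tr <- lapply(1:3, function(i) rbind(rep(c(0, 1, 2)[i], 10),
                                      rep(c(4, 0, 1)[i], 10)))
  te <- list(rbind(rep(0, 10), rep(0, 10)))
  row <- cross_kernel(epoch_set(tr, c("a", "b", "a")),
                      epoch_set(te, "a"),
                      c(0.25, 0.75), 0.5)
  expect_equal(as.numeric(row), expected, tolerance = 1e-12)
})
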