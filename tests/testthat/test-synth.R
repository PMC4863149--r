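test_that("invalid configurations are rejected naming the field", {
  expect_error(synth_config(n_informative = 9, n_electrodes = 8),
               "n_informative")
  expect_error(synth_config(template_len = 0), "template_len")
  expect_error(synth_config(warp_strength = 1.2), "warp_strength")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
  expect_error(synth_config(n_classes = 1), "n_classes")
})

test_that("templates are reproducible and respect informativeness", {
  cfg <- synth_config(n_electrodes = 5, n_informative = 2, seed = 4)
  t1 <- make_templates(cfg)
  t2 <- make_templates(cfg)
  expect_identical(t1, t2)                      # bit-identical from seed
  # informative electrodes differ between classes, the rest are shared
  for (e in 1:2) expect_false(isTRUE(all.equal(t1[1, e, ], t1[2, e, ])))
  for (e in 3:5) expect_equal(t1[1, e, ], t1[2, e, ])
  # n_informative = 0: no decodable signal anywhere
  t0 <- make_templates(synth_config(n_informative = 0, n_electrodes = 3,
                                    seed = 4))
  expect_equal(t0[1, , ], t0[2, , ])
  # single informative electrode: the class templates must differ
  tm <- make_templates(synth_config(n_electrodes = 1, n_informative = 1,
                                    seed = 4))
  expect_false(isTRUE(all.equal(tm[1, 1, ], tm[2, 1, ])))
})

test_that("identical configs give identical epoch sets", {
  cfg <- synth_config(n_trials_per_class = 4, n_electrodes = 3,
                      n_informative = 2, noise_sd = 1,
                      onset_jitter_sd = 0.1, warp_strength = 0.2,
                      epoch_mode = "cue_window", seed = 17)
  e1 <- generate_epochs(cfg)
  e2 <- generate_epochs(cfg)
  expect_identical(e1$trials, e2$trials)
  expect_identical(e1$true_onset, e2$true_onset)
})

test_that("the noise-free limit reproduces the class template exactly", {
  cfg <- synth_config(n_trials_per_class = 3, n_electrodes = 2,
                      n_informative = 2, noise_sd = 0, onset_jitter_sd = 0,
                      warp_strength = 0, seed = 2)
  tpl <- make_templates(cfg)
  es <- generate_epochs(cfg, tpl)
  pad <- round(0.1 * cfg$fs)
  L <- dim(tpl)[3]
  for (i in seq_along(es$trials)) {
    cl <- match(as.character(es$labels[i]), dimnames(tpl)[[1]])
    m <- es$trials[[i]]
    expect_equal(m[, pad + seq_len(L)], matrix(tpl[cl, , ], nrow = 2))
    expect_equal(m[, seq_len(pad)], matrix(0, 2, pad))  # onset pad
  }
})

test_that("onset jitter draws have the configured spread", {
  cfg <- synth_config(n_trials_per_class = 60, n_electrodes = 1,
                      n_informative = 0, noise_sd = 0,
                      onset_jitter_sd = 0.220, epoch_mode = "cue_window",
                      epoch_len = 3.5, base_onset = 1.2, seed = 5)
  es <- generate_epochs(cfg)
  delays <- es$true_onset - cfg$base_onset
  expect_lt(abs(sd(delays) - 0.220), 0.15 * 0.220)
})

test_that("time-locked trials have per-sample variance = noise variance", {
  cfg <- synth_config(n_trials_per_class = 150, n_electrodes = 1,
                      n_informative = 1, noise_sd = 0.7,
                      onset_jitter_sd = 0, warp_strength = 0, seed = 6)
  es <- generate_epochs(cfg)
  one <- which(es$labels == levels(es$labels)[1])
  X <- do.call(rbind, lapply(es$trials[one], function(m) m[1, ]))
  v <- apply(X, 2, var)
  expect_lt(abs(mean(v) - 0.7^2), 0.1 * 0.7^2)
})

test_that("responses overrunning the cue window are truncated and counted", {
  cfg <- synth_config(n_trials_per_class = 20, n_electrodes = 1,
                      n_informative = 1, noise_sd = 0,
                      onset_jitter_sd = 0.3, epoch_mode = "cue_window",
                      epoch_len = 1.2, base_onset = 0.4, seed = 10)
  expect_warning(es <- generate_epochs(cfg), "truncated")
  expect_gt(attr(es, "n_truncated"), 0)
  # fixed window length regardless of truncation
  expect_true(all(vapply(es$trials, ncol, integer(1)) ==
                    round(1.2 * 100)))
})

test_that("audio envelopes occupy exactly [onset, onset + duration)", {
  env <- generate_audio_envelope(0.5, 0.8, fs = 100)[[1]]
  expect_equal(sum(env > 0), 80)                # 0.8 s at 100 Hz
  tt <- (seq_along(env) - 1) / 100
  expect_true(all(env[tt < 0.5] == 0))
  expect_true(all(env[tt >= 1.3] == 0))
  expect_true(all(env >= 0))
  expect_equal(generate_audio_envelope(numeric(0), numeric(0)), list())
})

test_that("threshold detection recovers clean-envelope onsets to a sample", {
  fs <- 100
  envs <- generate_audio_envelope(c(0.5, 1.0, 0.73), c(0.8, 0.6, 0.8),
                                  fs = fs, trial_len = 2.5)
  truth <- list(c(0.5, 1.3), c(1.0, 1.6), c(0.73, 1.53))
  for (i in seq_along(envs)) {
    det <- detect_onset_offset(envs[[i]], fs)
    expect_lte(abs(det$onset - truth[[i]][1]), 1 / fs + 1e-9)
    expect_lte(abs(det$offset - truth[[i]][2]), 1 / fs + 1e-9)
  }
})

test_that("separability grows with informative electrodes, shrinks with noise", {
  acc <- function(n_inf, noise) {
    cfg <- synth_config(n_trials_per_class = 6, n_electrodes = 4,
                        n_informative = n_inf, noise_sd = noise, seed = 30)
    nested_loocv(generate_epochs(cfg),
                 gamma_grid = c(0.5, 1, 2), C_grid = c(0.1, 1, 10))$accuracy
  }
  expect_gte(acc(4, 0.4), acc(0, 0.4))
  expect_gte(acc(4, 0.4), acc(4, 4))
})
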