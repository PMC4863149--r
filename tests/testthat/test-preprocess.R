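rms <- function(x) sqrt(mean(x^2))

test_that("cleaning removes mains and DC but keeps in-band content", {
  fs <- 1000
  tt <- (0:(4 * fs - 1)) / fs
  rec <- signal_record(rbind(sin(2 * pi * 60 * tt),
                             sin(2 * pi * 100 * tt),
                             rep(2.5, length(tt))), fs)
  out <- clean_signal(rec)
  core <- (fs + 1):(3 * fs)                    # avoid filter edges
  expect_lt(rms(out$samples[1, core]), 0.01 * rms(rec$samples[1, core]))
  expect_gt(rms(out$samples[2, core]), 0.95 * rms(rec$samples[2, core]))
  expect_lt(max(abs(out$samples[3, core])), 1e-6)
  expect_error(clean_signal(signal_record(matrix(rnorm(500), 1), 500)),
               "180 Hz")
})

test_that("common average reference zeroes the per-sample channel mean", {
  x <- matrix(rnorm(400), 4)
  out <- common_average_reference(signal_record(x, 1000))
  expect_lt(max(abs(colMeans(out$samples))), 1e-12)
  # two identical channels cancel entirely
  same <- common_average_reference(signal_record(rbind(x[1, ], x[1, ]),
                                                 1000))
  expect_equal(same$samples, matrix(0, 2, ncol(x)), ignore_attr = TRUE)
  # already zero-mean input is untouched
  z <- rbind(x[1, ], -x[1, ])
  expect_equal(common_average_reference(signal_record(z, 1000))$samples, z,
               ignore_attr = TRUE)
  # idempotent
  expect_equal(common_average_reference(out)$samples, out$samples)
  expect_error(common_average_reference(signal_record(x[1, , drop = FALSE],
                                                      1000)), "2 channels")
})

test_that("high-gamma envelope tracks amplitude modulation in-band", {
  fs <- 1000
  tt <- (0:(6 * fs - 1)) / fs
  modl <- 1 + 0.8 * sin(2 * pi * 2 * tt)
  rec <- signal_record(rbind(modl * sin(2 * pi * 110 * tt),
                             sin(2 * pi * 30 * tt),
                             sin(2 * pi * 110 * tt)), fs)
  env <- extract_high_gamma(rec)
  expect_equal(env$fs, 100)
  expect_true(all(env$samples >= 0))
  n <- ncol(env$samples)
  core <- 51:(n - 50)
  mod100 <- 1 + 0.8 * sin(2 * pi * 2 * (core - 1) / 100)
  expect_gt(cor(env$samples[1, core], mod100), 0.95)
  # out-of-band tone is rejected; in-band tone has a flat envelope
  expect_lt(mean(env$samples[2, core]), 0.05 * mean(env$samples[3, core]))
  flat <- env$samples[3, core]
  expect_lt((max(flat) - min(flat)) / mean(flat), 0.05)
  expect_error(extract_high_gamma(signal_record(matrix(rnorm(30), 1),
                                                1000)), "shorter")
})

test_that("onset detection demands a sustained crossing of one utterance", {
  fs <- 100
  expect_error(detect_onset_offset(rep(0, 200), fs), "no speech")
  # two bursts: onset from the first, offset from the second
  env <- rep(0, 300)
  env[51:110] <- 1
  env[201:260] <- 1
  det <- detect_onset_offset(env, fs)
  expect_equal(det$onset, 0.5)
  expect_equal(det$offset, 2.59)
  # a 20 ms blip shorter than the sustain requirement is ignored
  blip <- rep(0, 300); blip[11:12] <- 1; blip[151:220] <- 0.9
  det2 <- detect_onset_offset(blip, fs)
  expect_equal(det2$onset, 1.5)
  expect_error(detect_onset_offset(c(-1, 1), fs), "nonnegative")
})

test_that("epoching follows the condition rules and baseline z-scoring", {
  fs <- 100
  nt <- 30 * fs
  set.seed(3)
  feat <- signal_record(matrix(abs(rnorm(2 * nt, 5, 1)), 2), fs)
  ev <- data.frame(word_label = c("spoon", "cowboy", "spoon"),
                   condition = "overt",
                   cue_onset = c(2, 10, 18),
                   speech_onset = c(3, 11, 19),
                   speech_offset = c(3.8, 11.8, 19.8))
  es <- epoch_and_zscore(feat, ev, "overt")
  # [onset - 0.1, offset + 0.1): 1.0 s -> 100 samples
  expect_true(all(vapply(es$trials, ncol, integer(1)) == 100))
  ev$condition <- "imagined"
  esi <- epoch_and_zscore(feat, ev, "imagined")
  expect_true(all(vapply(esi$trials, ncol, integer(1)) == 150))  # 1.5 s
  # z-scoring against the pooled pre-cue baseline: near 0 mean, unit SD
  z <- do.call(cbind, esi$trials)
  expect_lt(abs(mean(z)), 0.2)
  expect_lt(abs(sd(z) - 1), 0.2)
})

test_that("out-of-bounds trials are dropped with a reason", {
  fs <- 100
  feat <- signal_record(matrix(1 + abs(rnorm(2 * 10 * fs)), 2), fs)
  ev <- data.frame(word_label = c("spoon", "cowboy"),
                   condition = "imagined",
                   cue_onset = c(2, 9.5))          # second runs past the end
  expect_warning(es <- epoch_and_zscore(feat, ev, "imagined"), "dropped")
  expect_equal(length(es$trials), 1L)
  expect_match(attr(es, "dropped"), "trial 2")
  # constant baseline -> zero SD -> error
  const <- signal_record(matrix(1, 2, 10 * fs), fs)
  expect_error(epoch_and_zscore(const, ev[1, ], "imagined"),
               "zero baseline SD")
})

test_that("raw-voltage synthesis round-trips through the full chain", {
  cfg <- synth_config(n_trials_per_class = 8, n_electrodes = 8,
                      n_informative = 8, noise_sd = 0, onset_jitter_sd = 0,
                      warp_strength = 0, seed = 19)
  raw <- generate_raw_voltage(cfg, noise_uV = 0.05, mains_uV = 1)
  feat <- extract_high_gamma(common_average_reference(
    clean_signal(raw$signal)))
  es <- epoch_and_zscore(feat, raw$events, "overt")
  expect_equal(length(es$trials), 16L)
  # recovered per-class mean envelope matches the injected template;
  # epochs lead the response by the 100 ms pad, so scan a small lag range
  # around it (band-pass/decimation group delay shifts a sample or two)
  for (w in dimnames(raw$templates)[[1]]) {
    idx <- which(as.character(es$labels) == w)
    L <- min(vapply(es$trials[idx], ncol, integer(1)))
    avg <- Reduce(`+`, lapply(es$trials[idx],
                              function(m) m[, 1:L])) / length(idx)
    for (e in 1:8) {
      tpl <- raw$templates[w, e, ]
      cc <- vapply(8:16, function(lag) {
        m <- min(L, lag + length(tpl))
        cor(avg[e, (1 + lag):m], tpl[seq_len(m - lag)])
      }, numeric(1))
      expect_gt(max(cc), 0.8)
    }
  }
})
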