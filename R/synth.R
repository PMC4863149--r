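#' Configuration for the synthetic trial generator
#'
#' The generator emulates the statistical structure that the DTW-kernel
#' decoder assumes in real high-gamma recordings: per-class smooth
#' response templates on a subset of informative electrodes, trial-to-trial
#' speech-onset jitter, smooth monotone local time warping (local
#' stretching/compression of the response), and additive broadband noise
#' in z-units. Two epoching modes mirror the task conditions:
#' `"onset_locked"` epochs run from 100 ms before the true response onset
#' to 100 ms after its offset (as for listening/overt speech, where the
#' audio defines onsets); `"cue_window"` epochs are fixed windows starting
#' at the cue (as for imagined speech, where no onset is observable and
#' the jittered response sits somewhere inside the window).
#'
#' @param n_classes number of word classes (2: the decoder is pairwise).
#' @param n_trials_per_class trials per word.
#' @param n_electrodes total electrodes.
#' @param n_informative electrodes whose templates differ between classes
#'   (the rest share one template and carry no class signal).
#' @param fs feature sampling rate, samples/s (100, the post-decimation
#'   high-gamma rate).
#' @param template_len nominal response duration in seconds (0.8, matching
#'   the word length of the task stimuli, 800 ms +/- 20).
#' @param onset_jitter_sd SD of the per-trial onset delay in seconds
#'   (0 for time-locked stimuli; 0.220 emulates overt speech).
#' @param warp_strength maximal local rate deviation of the smooth
#'   monotone per-trial time warp; 0 disables warping, must be < 1.
#' @param noise_sd SD of additive Gaussian noise, in z-units.
#' @param epoch_mode `"onset_locked"` or `"cue_window"`.
#' @param epoch_len cue-window epoch length in seconds (1.5, the fixed
#'   imagined-speech epoch).
#' @param base_onset nominal response onset after the cue, seconds
#'   (cue-window mode).
#' @param ar_phi optional AR(1) coefficient colouring the noise (0 =
#'   white).
#' @param seed integer seed; the whole epoch set is reproducible from it.
#' @return an object of class `"synth_config"`.
#' @export
synth_config <- function(n_classes = 2L, n_trials_per_class = 10L,
                         n_electrodes = 8L, n_informative = 4L,
                         fs = 100, template_len = 0.8,
                         onset_jitter_sd = 0, warp_strength = 0,
                         noise_sd = 1, epoch_mode = c("onset_locked",
                                                      "cue_window"),
                         epoch_len = 1.5, base_onset = 0.25,
                         ar_phi = 0, seed = 1L) {
  epoch_mode <- match.arg(epoch_mode)
  chk <- function(ok, field, what) {
    if (!ok) stop("invalid '", field, "': ", what, call. = FALSE)
  }
  chk(is.numeric(n_classes) && n_classes >= 2, "n_classes", "need >= 2")
  chk(is.numeric(n_trials_per_class) && n_trials_per_class >= 1,
      "n_trials_per_class", "need >= 1")
  chk(is.numeric(n_electrodes) && n_electrodes >= 1, "n_electrodes",
      "need >= 1")
  chk(is.numeric(n_informative) && n_informative >= 0 &&
        n_informative <= n_electrodes, "n_informative",
      "need 0 <= n_informative <= n_electrodes")
  chk(is.numeric(fs) && fs > 0, "fs", "must be > 0")
  chk(is.numeric(template_len) && template_len > 0, "template_len",
      "must be > 0")
  chk(is.numeric(onset_jitter_sd) && onset_jitter_sd >= 0,
      "onset_jitter_sd", "must be >= 0")
  chk(is.numeric(warp_strength) && warp_strength >= 0 && warp_strength < 1,
      "warp_strength", "need 0 <= warp_strength < 1")
  chk(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(is.numeric(epoch_len) && epoch_len > 0, "epoch_len", "must be > 0")
  chk(is.numeric(base_onset) && base_onset >= 0, "base_onset",
      "must be >= 0")
  chk(is.numeric(ar_phi) && abs(ar_phi) < 1, "ar_phi", "need |ar_phi| < 1")
  structure(list(n_classes = as.integer(n_classes),
                 n_trials_per_class = as.integer(n_trials_per_class),
                 n_electrodes = as.integer(n_electrodes),
                 n_informative = as.integer(n_informative),
                 fs = fs, template_len = template_len,
                 onset_jitter_sd = onset_jitter_sd,
                 warp_strength = warp_strength, noise_sd = noise_sd,
                 epoch_mode = epoch_mode, epoch_len = epoch_len,
                 base_onset = base_onset, ar_phi = ar_phi,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# the six task words; used as class labels
.synth_words <- c("spoon", "cowboy", "battlefield", "swimming", "python",
                  "telephone")

#' Per-class, per-electrode response templates
#'
#' Builds smooth nonnegative amplitude templates (mixtures of 2-4 Gaussian
#' bumps) at the feature rate. The first `n_informative` electrodes get a
#' distinct template per class; the remaining electrodes share one
#' template across classes and therefore carry no class information.
#' Reproducible from `config$seed`.
#'
#' @param config a [synth_config()].
#' @return a 3-d array `[class, electrode, time]` with class and word
#'   dimnames.
#' @export
make_templates <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  L <- round(config$template_len * config$fs)
  set.seed(config$seed)
  words <- if (config$n_classes <= length(.synth_words))
    .synth_words[seq_len(config$n_classes)]
  else paste0("word", seq_len(config$n_classes))
  tpl <- array(0, dim = c(config$n_classes, config$n_electrodes, L),
               dimnames = list(words, NULL, NULL))
  tt <- seq_len(L)
  bump_mix <- function() {
    nb <- sample(2:4, 1L)
    v <- numeric(L)
    for (b in seq_len(nb)) {
      ctr <- runif(1, 0.1, 0.9) * L
      wid <- runif(1, 0.05, 0.15) * L
      amp <- runif(1, 0.8, 2)
      v <- v + amp * exp(-0.5 * ((tt - ctr) / wid)^2)
    }
    v
  }
  for (e in seq_len(config$n_electrodes)) {
    if (e <= config$n_informative) {
      for (cl in seq_len(config$n_classes)) tpl[cl, e, ] <- bump_mix()
    } else {
      shared <- bump_mix()
      for (cl in seq_len(config$n_classes)) tpl[cl, e, ] <- shared
    }
  }
  tpl
}

# smooth monotone warp: piecewise-linear rate in [1-w, 1+w] on 4 segments.
# .draw_warp samples the knot map once per trial; .apply_warp resamples a
# series through it (length changes with the realised mean rate), so all
# electrodes of a trial share one warp.
.draw_warp <- function(strength) {
  nseg <- 4L
  rate <- runif(nseg, 1 - strength, 1 + strength)
  u <- seq(0, 1, length.out = nseg + 1L)             # original time (norm.)
  w <- c(0, cumsum(rate * diff(u)))                  # warped time (norm.)
  list(u = u, w = w)
}

.apply_warp <- function(v, map) {
  L <- length(v)
  wK <- map$w[length(map$w)]
  Lw <- max(2L, round(L * wK))
  t_out <- seq(0, wK, length.out = Lw)
  t_orig <- approx(x = map$w, y = map$u, xout = t_out)$y  # invert knot map
  approx(x = seq(0, 1, length.out = L), y = v, xout = t_orig)$y
}

.ar1_noise <- function(n, sd, phi) {
  e <- rnorm(n, 0, sd)
  if (phi == 0) return(e)
  x <- as.numeric(stats::filter(e, phi, method = "recursive"))
  x * sqrt(1 - phi^2)                                # keep marginal SD = sd
}

#' Generate a synthetic epoch set with ground-truth onsets
#'
#' Each trial is its class template, time-warped by a smooth monotone warp
#' with local rate in `[1 - warp_strength, 1 + warp_strength]`, shifted by
#' an onset delay drawn from `N(0, onset_jitter_sd^2)`, plus additive
#' noise. In `onset_locked` mode each epoch runs from 100 ms before the
#' true onset to 100 ms after the true offset (so epochs are aligned but
#' lengths vary with the warp); in `cue_window` mode epochs are fixed
#' `epoch_len` windows starting at the cue, with the jittered response
#' inside (responses extending beyond the window are truncated and
#' counted).
#'
#' @param config a [synth_config()].
#' @param templates optional array from [make_templates()]; regenerated
#'   from the config seed when missing.
#' @return an [epoch_set()] with extra fields `true_onset` (seconds after
#'   the cue), `duration` (realised response duration), `config`, and
#'   attribute `n_truncated`.
#' @export
generate_epochs <- function(config, templates = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(templates)) templates <- make_templates(config)
  fs <- config$fs
  pad <- round(0.1 * fs)
  n_trial <- config$n_classes * config$n_trials_per_class
  classes <- rep(seq_len(config$n_classes), each = config$n_trials_per_class)
  words <- dimnames(templates)[[1L]]
  set.seed(config$seed + 1L)
  trials <- vector("list", n_trial)
  true_onset <- duration <- numeric(n_trial)
  n_trunc <- 0L
  for (i in seq_len(n_trial)) {
    cl <- classes[i]
    # one warp and one delay per trial, common to all electrodes (the
    # response is a single behavioural event seen by every electrode)
    tpl_cl <- matrix(templates[cl, , ], nrow = config$n_electrodes)
    if (config$warp_strength > 0) {
      map <- .draw_warp(config$warp_strength)
      resp <- do.call(rbind, lapply(seq_len(config$n_electrodes),
                                    function(e) .apply_warp(tpl_cl[e, ],
                                                            map)))
    } else {
      resp <- tpl_cl
    }
    Lr <- ncol(resp)
    delay <- if (config$onset_jitter_sd > 0)
      rnorm(1, 0, config$onset_jitter_sd) else 0
    onset <- config$base_onset + delay
    if (config$epoch_mode == "onset_locked") {
      ep <- matrix(0, config$n_electrodes, Lr + 2L * pad)
      ep[, pad + seq_len(Lr)] <- resp
    } else {
      Lw <- round(config$epoch_len * fs)
      ep <- matrix(0, config$n_electrodes, Lw)
      i0 <- round(onset * fs)                        # 0-based sample offset
      src <- seq_len(Lr)
      dst <- i0 + src
      keep <- dst >= 1L & dst <= Lw
      if (!all(keep)) n_trunc <- n_trunc + 1L
      ep[, dst[keep]] <- resp[, src[keep], drop = FALSE]
    }
    if (config$noise_sd > 0)
      ep <- ep + matrix(.ar1_noise(length(ep), config$noise_sd,
                                   config$ar_phi),
                        nrow = nrow(ep))
    trials[[i]] <- ep
    true_onset[i] <- onset
    duration[i] <- Lr / fs
  }
  if (n_trunc > 0)
    warning(n_trunc, " trial(s) truncated at the cue-window boundary")
  es <- epoch_set(trials, words[classes], fs_feat = fs,
                  condition = "synthetic")
  es$true_onset <- true_onset
  es$duration <- duration
  es$config <- config
  attr(es, "n_truncated") <- n_trunc
  es
}

#' Synthetic audio-like speech envelopes
#'
#' Builds one smooth, unimodal, nonnegative envelope per trial, occupying
#' exactly `[onset, onset + duration)` and zero elsewhere: a flat bump
#' with short raised-cosine ramps at both ends (steep enough that a 10%
#' threshold is crossed within the first ramp samples, so envelope
#' threshold detection recovers the onset to within one sample on clean
#' data).
#'
#' @param onsets numeric vector of onset times, seconds.
#' @param durations numeric vector (recycled) of utterance durations,
#'   seconds.
#' @param fs sampling rate of the envelope channel.
#' @param trial_len common trial length in seconds; defaults to covering
#'   the latest offset plus 0.2 s.
#' @param ramp_s rise/fall ramp duration, seconds.
#' @return a list of numeric envelope vectors (empty list for zero
#'   trials).
#' @export
generate_audio_envelope <- function(onsets, durations, fs = 100,
                                    trial_len = NULL, ramp_s = 0.02) {
  if (length(onsets) == 0L) return(list())
  durations <- rep_len(durations, length(onsets))
  if (any(onsets < 0)) stop("onsets must be >= 0")
  if (any(durations <= 0)) stop("durations must be > 0")
  if (is.null(trial_len)) trial_len <- max(onsets + durations) + 0.2
  n <- round(trial_len * fs)
  tt <- (seq_len(n) - 1) / fs
  lapply(seq_along(onsets), function(i) {
    env <- numeric(n)
    sup <- which(tt >= onsets[i] & tt < onsets[i] + durations[i])
    m <- length(sup)
    if (m > 0) {
      r <- max(1L, min(round(ramp_s * fs), floor(m / 2)))
      w <- rep(1, m)
      up <- sin(pi / 2 * seq_len(r) / r)^2
      w[seq_len(r)] <- up
      w[m + 1L - seq_len(r)] <- up
      env[sup] <- w
    }
    env
  })
}

#' Synthesize a raw-voltage recording from the generator's templates
#'
#' Raw-voltage mode exists to exercise the full preprocessing chain end to
#' end: each electrode's high-gamma amplitude (baseline plus the warped,
#' jittered class template) modulates a carrier tone inside the 70-150 Hz
#' band, with added broadband noise and 60 Hz mains interference, sampled
#' at `fs_raw`. Trials are laid out on a continuous timeline with one cue
#' per trial, and an event table in the package's TSV layout is returned
#' alongside, so `clean_signal()` -> `common_average_reference()` ->
#' `extract_high_gamma()` -> `epoch_and_zscore()` can recover the injected
#' templates.
#'
#' @param config a [synth_config()].
#' @param fs_raw raw sampling rate, samples/s (>= 1000).
#' @param noise_uV broadband noise SD on the raw scale.
#' @param mains_uV amplitude of the 60 Hz mains component.
#' @param gap_s quiet time between trials, seconds.
#' @return a list with `signal` (a [signal_record()]), `events` (a
#'   data.frame with `word_label`, `condition`, `cue_onset`,
#'   `speech_onset`, `speech_offset`), `templates`, and the per-trial
#'   `true_onset`/`duration` (seconds, absolute).
#' @export
generate_raw_voltage <- function(config, fs_raw = 1000, noise_uV = 0.5,
                                 mains_uV = 1, gap_s = 1.5) {
  stopifnot(inherits(config, "synth_config"))
  if (fs_raw < 1000) stop("'fs_raw' must be >= 1000 samples/s")
  feats <- generate_epochs(config)            # feature-rate ground truth
  templates <- make_templates(config)
  fs <- config$fs
  n_trial <- length(feats)
  slot <- config$epoch_len + gap_s
  cue <- gap_s + (seq_len(n_trial) - 1) * slot
  total_s <- gap_s + n_trial * slot
  nt <- round(total_s * fs_raw)
  tt <- (seq_len(nt) - 1) / fs_raw
  ne <- config$n_electrodes
  set.seed(config$seed + 2L)
  # high-gamma is broadband: each electrode's carrier is independent
  # band-limited (70-150 Hz) unit-SD noise, so channels stay mutually
  # incoherent (also under common-average referencing) and cross terms
  # average out over trials
  bp <- signal::butter(4, c(70, 150) / (fs_raw / 2), type = "pass")
  carrier <- t(vapply(seq_len(ne), function(e) {
    v <- signal::filtfilt(bp, rnorm(nt))
    v / sd(v)
  }, numeric(nt)))
  amp <- matrix(0.2, ne, nt)                  # resting high-gamma level
  for (i in seq_len(n_trial)) {
    ep <- feats$trials[[i]]
    # amplitude follows the noiseless response; strip the generator noise
    cl <- which(dimnames(templates)[[1L]] == as.character(feats$labels[i]))
    Lr <- round(feats$duration[i] * fs)
    resp <- matrix(templates[cl, , ], nrow = ne)
    on_abs <- cue[i] + feats$true_onset[i]
    idx0 <- round(on_abs * fs_raw)
    t_resp <- seq_len(round(feats$duration[i] * fs_raw))
    src <- pmin(ncol(resp), pmax(1L, ceiling(t_resp * fs / fs_raw)))
    dst <- idx0 + t_resp
    keep <- dst >= 1L & dst <= nt
    amp[, dst[keep]] <- amp[, dst[keep]] + resp[, src[keep], drop = FALSE]
  }
  sig <- matrix(0, ne, nt)
  for (e in seq_len(ne)) {
    sig[e, ] <- amp[e, ] * carrier[e, ] +
      mains_uV * sin(2 * pi * 60 * tt) +
      rnorm(nt, 0, noise_uV)
  }
  events <- data.frame(
    word_label = as.character(feats$labels),
    condition = "overt",
    cue_onset = cue,
    speech_onset = cue + feats$true_onset,
    speech_offset = cue + feats$true_onset + feats$duration,
    stringsAsFactors = FALSE)
  list(signal = signal_record(sig, fs_raw,
                              paste0("E", seq_len(ne))),
       events = events, templates = templates,
       true_onset = cue + feats$true_onset, duration = feats$duration)
}
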