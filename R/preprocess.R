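#' Construct a continuous multichannel signal record
#'
#' @param samples electrodes x time numeric matrix (uV or arbitrary
#'   units).
#' @param fs sampling rate, samples/s.
#' @param channel_labels optional character vector, one label per channel.
#' @return an object of class `"signal_record"`.
#' @export
signal_record <- function(samples, fs, channel_labels = NULL) {
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1L)
  samples <- as.matrix(samples)
  if (!is.numeric(fs) || fs <= 0) stop("'fs' must be > 0")
  if (anyNA(samples)) stop("signal contains NA values")
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(samples)))
  if (length(channel_labels) != nrow(samples))
    stop("'channel_labels' must have one entry per channel")
  structure(list(samples = samples, fs = fs,
                 channel_labels = as.character(channel_labels)),
            class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat("Signal record: ", nrow(x$samples), " channels x ", ncol(x$samples),
      " samples @ ", x$fs, " Hz (", round(ncol(x$samples) / x$fs, 2),
      " s)\n", sep = "")
  invisible(x)
}

.filtfilt_rows <- function(filt, samples) {
  t(apply(samples, 1L, function(v) signal::filtfilt(filt, v)))
}

#' Clean a raw recording: DC removal, band-pass and mains notches
#'
#' Removes the per-channel DC offset, band-pass filters 0.5-200 Hz
#' (Butterworth, zero-phase forward-backward), and notches the 60, 120 and
#' 180 Hz mains lines (second-order Butterworth band-stops, +/- 2 Hz,
#' zero-phase). Re-referencing is a separate step
#' ([common_average_reference()]) so the montage choice stays explicit.
#'
#' @param raw a [signal_record()] sampled at >= 1000 samples/s (the 180 Hz
#'   notch needs the Nyquist headroom).
#' @return a cleaned `signal_record` at the same rate.
#' @export
clean_signal <- function(raw) {
  stopifnot(inherits(raw, "signal_record"))
  if (raw$fs < 1000)
    stop("sampling rate ", raw$fs,
         " is too low to place the 180 Hz notch; need fs >= 1000")
  ny <- raw$fs / 2
  x <- raw$samples - rowMeans(raw$samples)
  hp <- signal::butter(2, 0.5 / ny, type = "high")
  lp <- signal::butter(4, 200 / ny, type = "low")
  x <- .filtfilt_rows(hp, x)
  x <- .filtfilt_rows(lp, x)
  for (f0 in c(60, 120, 180)) {
    ntch <- signal::butter(2, c(f0 - 2, f0 + 2) / ny, type = "stop")
    x <- .filtfilt_rows(ntch, x)
  }
  signal_record(x, raw$fs, raw$channel_labels)
}

#' Common average reference
#'
#' Subtracts, at every sample, the mean across channels; afterwards the
#' per-sample channel mean is exactly zero (the operation is idempotent).
#'
#' @param signal a [signal_record()] with at least 2 channels.
#' @return a re-referenced `signal_record`.
#' @export
common_average_reference <- function(signal) {
  stopifnot(inherits(signal, "signal_record"))
  if (nrow(signal$samples) < 2L)
    stop("common average reference needs at least 2 channels")
  x <- sweep(signal$samples, 2L, colMeans(signal$samples))
  signal_record(x, signal$fs, signal$channel_labels)
}

# analytic signal magnitude via the FFT construction
.envelope <- function(v) {
  n <- length(v)
  F <- fft(v)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(F * h, inverse = TRUE) / n)
}

#' High-gamma envelope features at 100 samples/s
#'
#' Band-pass filters each channel in the high-gamma band (70-150 Hz;
#' Hamming-window FIR of order 20, applied zero-phase forward-backward),
#' takes the analytic-signal magnitude as the envelope, and decimates with
#' an anti-aliasing low-pass to the feature rate. Output is clamped
#' nonnegative (decimation filtering can undershoot zero by a ripple).
#'
#' @param signal a cleaned [signal_record()] at >= 1000 samples/s; `fs`
#'   must be an integer multiple of `fs_out`.
#' @param fs_out feature rate, samples/s (default 100).
#' @param order FIR order of the band-pass (default 20; note that order 20
#'   at 1 kHz gives a shallow transition band).
#' @param band high-gamma band edges in Hz.
#' @return a `signal_record` of nonnegative envelope features at `fs_out`.
#' @export
extract_high_gamma <- function(signal, fs_out = 100, order = 20,
                               band = c(70, 150)) {
  stopifnot(inherits(signal, "signal_record"))
  if (signal$fs < 1000) stop("need fs >= 1000 samples/s")
  if (signal$fs %% fs_out != 0)
    stop("'fs' must be an integer multiple of 'fs_out'")
  n <- ncol(signal$samples)
  if (n <= 3 * (order + 1))
    stop("signal shorter than the filter length")
  ny <- signal$fs / 2
  b <- signal::fir1(order, band / ny, type = "pass",
                    window = signal::hamming(order + 1))
  q <- signal$fs / fs_out
  feat <- t(apply(signal$samples, 1L, function(v) {
    env <- .envelope(signal::filtfilt(b, v))
    pmax(0, signal::decimate(env, q, ftype = "fir"))
  }))
  signal_record(feat, fs_out, signal$channel_labels)
}

#' Envelope-based speech onset and offset detection
#'
#' Onset is the first time the (optionally smoothed) envelope exceeds a
#' threshold — a fraction of the trial maximum — sustained for at least
#' `sustain_s`; offset is the last time of the last such sustained
#' stretch. A single utterance per trial is assumed: with two bursts the
#' onset comes from the first and the offset from the second.
#'
#' @param audio_envelope nonnegative numeric envelope vector.
#' @param fs sampling rate of the envelope.
#' @param threshold fraction of the trial maximum (default 0.1).
#' @param sustain_s minimum above-threshold duration in seconds (default
#'   0.05).
#' @param smooth_s moving-average smoothing window in seconds (0 = none).
#' @return a list with `onset` and `offset` in seconds (times of the
#'   first/last qualifying samples, 0-based).
#' @export
detect_onset_offset <- function(audio_envelope, fs, threshold = 0.1,
                                sustain_s = 0.05, smooth_s = 0) {
  env <- as.numeric(audio_envelope)
  if (any(env < 0)) stop("envelope must be nonnegative")
  if (smooth_s > 0) {
    w <- max(1L, round(smooth_s * fs))
    env <- as.numeric(stats::filter(env, rep(1 / w, w), sides = 2))
    env[is.na(env)] <- 0
  }
  thr <- threshold * max(env)
  above <- env > thr
  if (!any(above)) stop("no speech detected: envelope never crosses the ",
                        "threshold")
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= max(1L, round(sustain_s * fs))
  if (!any(keep)) stop("no speech detected: no sustained ",
                       "above-threshold stretch")
  list(onset = (starts[keep][1L] - 1L) / fs,
       offset = (ends[keep][sum(keep)] - 1L) / fs)
}

#' Epoch continuous features and z-score against the pre-stimulus baseline
#'
#' Cuts per-trial windows out of continuous feature channels —
#' `[speech_onset - pad_s, speech_offset + pad_s)` for listening/overt
#' trials, fixed `[cue_onset, cue_onset + epoch_len_s)` windows for
#' imagined trials — and z-scores each electrode using baseline statistics
#' from the `baseline_s` window preceding each auditory stimulus (cue),
#' pooled across trials (per-trial baselines via
#' `baseline_mode = "per_trial"`). Windows are half-open, in seconds,
#' 0-based.
#'
#' @param features a [signal_record()] of envelope features (typically
#'   from [extract_high_gamma()]).
#' @param events a data.frame with columns `word_label`, `condition`,
#'   `cue_onset`, and (for listening/overt) `speech_onset`,
#'   `speech_offset`, all times in seconds.
#' @param condition `"listening"`, `"overt"` or `"imagined"`.
#' @param baseline_s pre-stimulus baseline duration (default 0.5).
#' @param pad_s pad around speech onset/offset (default 0.1).
#' @param epoch_len_s fixed epoch length for imagined trials (default
#'   1.5).
#' @param baseline_mode `"pooled"` (default) or `"per_trial"`.
#' @return an [epoch_set()]; trials whose window leaves the recording are
#'   dropped with a warning, and the drop reasons are kept in attribute
#'   `"dropped"`.
#' @export
epoch_and_zscore <- function(features, events, condition,
                             baseline_s = 0.5, pad_s = 0.1,
                             epoch_len_s = 1.5,
                             baseline_mode = c("pooled", "per_trial")) {
  stopifnot(inherits(features, "signal_record"))
  baseline_mode <- match.arg(baseline_mode)
  condition <- match.arg(condition, c("listening", "overt", "imagined"))
  events <- .validate_events(events, condition)
  fs <- features$fs
  nmax <- ncol(features$samples)
  win_idx <- function(from, to) {
    i0 <- round(from * fs) + 1L
    i1 <- round(to * fs)
    if (i0 < 1L || i1 > nmax || i1 < i0) return(NULL)
    i0:i1
  }
  # per-trial epoch windows
  wins <- lapply(seq_len(nrow(events)), function(i) {
    if (condition == "imagined")
      win_idx(events$cue_onset[i], events$cue_onset[i] + epoch_len_s)
    else
      win_idx(events$speech_onset[i] - pad_s,
              events$speech_offset[i] + pad_s)
  })
  bases <- lapply(seq_len(nrow(events)), function(i)
    win_idx(events$cue_onset[i] - baseline_s, events$cue_onset[i]))
  ok <- !vapply(wins, is.null, logical(1)) &
    !vapply(bases, is.null, logical(1))
  dropped <- character(0)
  if (any(!ok)) {
    dropped <- sprintf("trial %d (%s): window outside recording bounds",
                       which(!ok), events$word_label[!ok])
    warning(sum(!ok), " trial(s) dropped: window outside recording bounds")
  }
  if (!any(ok)) stop("no trials left after bounds check")
  zs <- function(m, mu, sdv) (m - mu) / sdv
  if (baseline_mode == "pooled") {
    bl <- do.call(cbind, lapply(which(ok), function(i)
      features$samples[, bases[[i]], drop = FALSE]))
    mu <- rowMeans(bl)
    sdv <- apply(bl, 1L, sd)
    if (any(sdv == 0)) stop("zero baseline SD on electrode(s) ",
                            paste(which(sdv == 0), collapse = ", "))
    trials <- lapply(which(ok), function(i)
      zs(features$samples[, wins[[i]], drop = FALSE], mu, sdv))
  } else {
    trials <- lapply(which(ok), function(i) {
      bl <- features$samples[, bases[[i]], drop = FALSE]
      mu <- rowMeans(bl)
      sdv <- apply(bl, 1L, sd)
      if (any(sdv == 0)) stop("zero baseline SD on electrode(s) ",
                              paste(which(sdv == 0), collapse = ", "),
                              " in trial ", i)
      zs(features$samples[, wins[[i]], drop = FALSE], mu, sdv)
    })
  }
  es <- epoch_set(trials, events$word_label[ok], fs_feat = fs,
                  condition = condition)
  attr(es, "dropped") <- dropped
  es
}

.validate_events <- function(events, condition = NULL) {
  events <- as.data.frame(events)
  need <- c("word_label", "condition", "cue_onset")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("event table is missing column(s): ", paste(miss, collapse = ", "))
  if (!is.null(condition)) {
    events <- events[events$condition == condition, , drop = FALSE]
    if (nrow(events) == 0L) stop("no trials for condition '", condition,
                                 "'")
    if (condition != "imagined") {
      if (!all(c("speech_onset", "speech_offset") %in% names(events)))
        stop("listening/overt trials need speech_onset and speech_offset")
      bad <- !is.na(events$speech_onset) & !is.na(events$speech_offset) &
        events$speech_onset >= events$speech_offset
      if (any(bad)) stop("speech_onset must be < speech_offset")
    }
  }
  events
}
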