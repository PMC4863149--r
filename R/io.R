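#' Read a multichannel signal from a TSV matrix
#'
#' The on-disk signal format is a plain tab-separated matrix: one column
#' per channel, a header row of channel labels, one row per sample. The
#' sampling rate travels alongside (argument or a `# fs=<Hz>` first-line
#' comment written by [write_signal_tsv()]).
#'
#' @param path file path.
#' @param fs sampling rate in samples/s; taken from the file's `# fs=`
#'   comment when missing.
#' @return a [signal_record()].
#' @export
read_signal_tsv <- function(path, fs = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(fs)) {
    m <- regmatches(first, regexec("^#\\s*fs=([0-9.]+)", first))[[1L]]
    if (length(m) < 2L)
      stop("no 'fs' argument and no '# fs=' header in ", path)
    fs <- as.numeric(m[2L])
  }
  df <- read.delim(path, comment.char = "#", check.names = FALSE)
  signal_record(t(as.matrix(df)), fs, colnames(df))
}

#' Write a signal record to a TSV matrix
#' @param signal a [signal_record()].
#' @param path file path.
#' @export
write_signal_tsv <- function(signal, path) {
  stopifnot(inherits(signal, "signal_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# fs=", signal$fs), con)
  df <- as.data.frame(t(signal$samples))
  names(df) <- signal$channel_labels
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Read a trial event table from TSV
#'
#' Expected columns: `word_label`, `condition` (listening/overt/imagined),
#' `cue_onset` and, for listening/overt trials, `speech_onset` and
#' `speech_offset` (seconds).
#'
#' @param path file path.
#' @return a validated data.frame.
#' @export
read_events_tsv <- function(path) {
  .validate_events(read.delim(path, stringsAsFactors = FALSE))
}

#' Write an epoch set as per-trial matrices plus a TSV manifest
#'
#' Each trial is written as `trial_<id>.tsv` (electrodes x time, tab
#' separated); `manifest.tsv` lists `trial_id`, `class`, `condition`,
#' `true_onset_s` (NA when unknown) and `n_samples`.
#'
#' @param epochs an [epoch_set()].
#' @param dir output directory (created if needed).
#' @export
write_epochs <- function(epochs, dir) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(epochs$trials)
  ids <- sprintf("trial_%03d", seq_len(n))
  for (i in seq_len(n))
    write.table(epochs$trials[[i]], file.path(dir, paste0(ids[i], ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  manifest <- data.frame(
    trial_id = ids, class = as.character(epochs$labels),
    condition = epochs$condition,
    true_onset_s = if (is.null(epochs$true_onset)) NA_real_
                   else epochs$true_onset,
    n_samples = vapply(epochs$trials, ncol, integer(1)))
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an epoch set written by [write_epochs()]
#' @param dir directory containing `manifest.tsv` and per-trial TSVs.
#' @param fs_feat feature sampling rate of the stored epochs.
#' @return an [epoch_set()].
#' @export
read_epochs <- function(dir, fs_feat = 100) {
  manifest <- read.delim(file.path(dir, "manifest.tsv"),
                         stringsAsFactors = FALSE)
  trials <- lapply(manifest$trial_id, function(id)
    as.matrix(read.delim(file.path(dir, paste0(id, ".tsv")),
                         header = FALSE)))
  es <- epoch_set(trials, manifest$class, fs_feat = fs_feat,
                  condition = manifest$condition[1L])
  if (!all(is.na(manifest$true_onset_s)))
    es$true_onset <- manifest$true_onset_s
  es
}

#' Write a trial distance matrix as TSV with trial-id headers
#' @param D a distance matrix (e.g. from [pairwise_dtw()]).
#' @param path file path.
#' @export
write_distance_tsv <- function(D, path) {
  M <- unclass(as.matrix(D))
  ids <- attr(D, "trial_ids")
  if (is.null(ids)) ids <- sprintf("trial_%03d", seq_len(nrow(M)))
  dimnames(M) <- list(ids, ids)
  write.table(M, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a trial distance matrix written by [write_distance_tsv()]
#' @param path file path.
#' @return a distance matrix with `trial_ids` attribute.
#' @export
read_distance_tsv <- function(path) {
  df <- read.delim(path, row.names = 1L, check.names = FALSE)
  .as_distance_matrix(as.matrix(df), electrode = NA_integer_,
                      trial_ids = rownames(df))
}
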