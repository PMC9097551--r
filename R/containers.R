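#' Continuous multichannel recording
#'
#' Thin S3 container for a continuous EEG session: a channels x samples
#' matrix in microvolts plus sampling rate, channel metadata, and event
#' markers (cue onset, Go-Cue, movement onset) with per-trial labels.
#'
#' @param data channels x samples numeric matrix (microvolts), rownames are
#'   channel labels.
#' @param fs sampling rate in Hz.
#' @param ch_types character vector, one of `"eeg"`, `"ref"`, `"eog"` per
#'   channel.
#' @param events data.frame with one row per trial: `cue_sample`,
#'   `go_sample`, `onset_sample` (1-based sample indices), `primary`
#'   ("L"/"R") and `opposite` ("F"/"B") labels.
#' @param meta optional list of generator / provenance metadata.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(data, fs, ch_types, events, meta = list()) {
  stopifnot(is.matrix(data), fs > 0, !is.null(rownames(data)),
            length(ch_types) == nrow(data))
  structure(list(data = data, fs = fs,
                 ch_names = rownames(data), ch_types = ch_types,
                 events = events, meta = meta),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat(sprintf("  eeg: %d  ref: %d  eog: %d; %d trials\n",
              sum(x$ch_types == "eeg"), sum(x$ch_types == "ref"),
              sum(x$ch_types == "eog"), nrow(x$events)))
  invisible(x)
}

eeg_channels <- function(rec) which(rec$ch_types == "eeg")
eog_channels <- function(rec) which(rec$ch_types == "eog")

#' Epoched EEG data
#'
#' S3 container for epoched trials: a trials x channels x time array with a
#' time axis relative to the Go-Cue, per-trial direction labels, and a
#' provenance record listing the preprocessing applied.
#'
#' @param data trials x channels x time numeric array.
#' @param fs sampling rate in Hz.
#' @param ch_names channel labels (length = dim(data)[2]).
#' @param times numeric vector of sample times in seconds relative to the
#'   Go-Cue (length = dim(data)[3]).
#' @param labels data.frame with columns `primary` and `opposite`.
#' @param provenance list of applied preprocessing steps and parameters.
#' @return An object of class `eeg_epochs`.
#' @export
new_epochs <- function(data, fs, ch_names, times, labels,
                       provenance = list()) {
  stopifnot(length(dim(data)) == 3,
            dim(data)[2] == length(ch_names),
            dim(data)[3] == length(times),
            dim(data)[1] == nrow(labels))
  dimnames(data) <- list(NULL, ch_names, NULL)
  structure(list(data = data, fs = fs, ch_names = ch_names,
                 times = times, labels = labels, provenance = provenance),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz, t in [%g, %g] s\n",
    d[1], d[2], d[3], x$fs, min(x$times), max(x$times)))
  if (length(x$provenance))
    cat("  steps:", paste(vapply(x$provenance, `[[`, "", "step"),
                          collapse = " -> "), "\n")
  invisible(x)
}

add_provenance <- function(epochs, step, params = list()) {
  epochs$provenance <- c(epochs$provenance,
                         list(c(list(step = step), params)))
  epochs
}

channel_index <- function(x, channel) {
  i <- match(channel, x$ch_names)
  if (anyNA(i)) stop("channel not in montage: ",
                     paste(channel[is.na(i)], collapse = ", "))
  i
}
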