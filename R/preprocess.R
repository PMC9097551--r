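#' Preprocessing configuration
#'
#' Parameters of the fixed preprocessing chain applied before feature
#' extraction: down-sampling, re-referencing to the mastoid-proxy
#' ("binaural") channels, per-trial baseline correction, common average
#' reference, ICA-based ocular artifact rejection, band-pass filtering and
#' epoching around the Go-Cue.
#'
#' @param target_fs target sampling rate in Hz (default 100).
#' @param reference_channels labels of the reference channels whose mean is
#'   subtracted (default the synthetic mastoid proxies "M1", "M2").
#' @param baseline_window seconds relative to the Go-Cue over which the
#'   per-trial, per-channel mean is removed (default `c(-2, 0)`, the flat
#'   pre-movement period).
#' @param car apply the common average reference (default TRUE).
#' @param ica_corr_threshold absolute Pearson correlation with an EOG
#'   channel above which (strictly) an independent component is rejected
#'   (default 0.4).
#' @param band band-pass edges in Hz (default `c(0.01, 4)`).
#' @param filter_kind `"fft"` (brick-wall Fourier mask, the decoding path)
#'   or `"butterworth"` (4th-order zero-phase, the waveform-visualization
#'   path).
#' @param epoch_window epoch limits in seconds relative to the Go-Cue
#'   (default `c(0, 1)`, i.e. `[-0.5, 0.5]` s of actual movement onset).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_fs = 100,
                              reference_channels = c("M1", "M2"),
                              baseline_window = c(-2, 0),
                              car = TRUE,
                              ica_corr_threshold = 0.4,
                              band = c(0.01, 4),
                              filter_kind = c("fft", "butterworth"),
                              epoch_window = c(0, 1)) {
  filter_kind <- match.arg(filter_kind)
  stopifnot(target_fs > 0, length(band) == 2)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < target_fs / 2))
    stop("band must satisfy 0 < low < high < target_fs/2")
  if (ica_corr_threshold < 0 || ica_corr_threshold > 1)
    stop("ica_corr_threshold must lie in [0, 1]")
  structure(list(target_fs = target_fs,
                 reference_channels = reference_channels,
                 baseline_window = baseline_window, car = car,
                 ica_corr_threshold = ica_corr_threshold, band = band,
                 filter_kind = filter_kind, epoch_window = epoch_window),
            class = "preprocess_config")
}

# zero-phase filtering with odd reflection padding to suppress edge
# transients (signal::filtfilt does not pad)
pad_filtfilt <- function(flt, x) {
  n <- length(x)
  p <- min(1000L, n - 1L)
  xp <- c(2 * x[1] - rev(x[2:(p + 1)]), x, 2 * x[n] - rev(x[(n - p):(n - 1)]))
  signal::filtfilt(flt, xp)[p + seq_len(n)]
}

#' Down-sample a recording
#'
#' Anti-alias filters (8th-order zero-phase Butterworth at 0.8 of the new
#' Nyquist) and decimates every channel; event marker samples are
#' re-indexed to the new rate. Only integer decimation factors are
#' supported; upsampling is refused.
#'
#' @param rec an `eeg_recording`.
#' @param target_fs new sampling rate in Hz; must divide `rec$fs`.
#' @return The resampled `eeg_recording`.
#' @export
resample_recording <- function(rec, target_fs) {
  if (target_fs > rec$fs)
    stop("upsampling is unsupported (target_fs > fs)")
  if (target_fs == rec$fs) return(rec)
  q <- rec$fs / target_fs
  if (abs(q - round(q)) > 1e-9)
    stop("fs / target_fs must be an integer decimation factor")
  q <- as.integer(round(q))
  aa <- signal::butter(8, 0.8 / q, "low")
  keep <- seq(1, ncol(rec$data), by = q)
  out <- matrix(0, nrow = nrow(rec$data), ncol = length(keep))
  rownames(out) <- rec$ch_names
  for (i in seq_len(nrow(rec$data)))
    out[i, ] <- pad_filtfilt(aa, rec$data[i, ])[keep]
  rec$data <- out
  for (col in c("cue_sample", "go_sample", "onset_sample"))
    if (col %in% names(rec$events))
      rec$events[[col]] <- as.integer(round((rec$events[[col]] - 1L) / q) + 1L)
  rec$fs <- target_fs
  rec
}

#' Re-reference to the mean of designated reference channels
#'
#' Subtracts the samplewise mean of the reference channels from every EEG
#' and reference channel (EOG channels are left untouched), emulating
#' re-referencing to linked mastoids.
#'
#' @param rec an `eeg_recording`.
#' @param reference_channels labels of the reference channels.
#' @return The re-referenced `eeg_recording`.
#' @export
rereference <- function(rec, reference_channels = c("M1", "M2")) {
  idx <- match(reference_channels, rec$ch_names)
  if (anyNA(idx))
    stop("reference channel(s) not present: ",
         paste(reference_channels[is.na(idx)], collapse = ", "))
  ref <- colMeans(rec$data[idx, , drop = FALSE])
  target <- which(rec$ch_types != "eog")
  rec$data[target, ] <- sweep(rec$data[target, , drop = FALSE], 2, ref)
  rec
}

#' Baseline-correct epochs
#'
#' Per trial and channel, subtracts the mean over the baseline window.
#'
#' @param epochs an `eeg_epochs`.
#' @param baseline_window seconds relative to the Go-Cue; must overlap the
#'   epoch time axis.
#' @return Corrected `eeg_epochs`.
#' @export
baseline_correct <- function(epochs, baseline_window = c(-2, 0)) {
  sel <- epochs$times >= baseline_window[1] & epochs$times < baseline_window[2]
  if (!any(sel))
    stop("baseline window contains no samples of the epoch time axis")
  mu <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(mu)  # recycles over time (3rd dim)
  add_provenance(epochs, "baseline_correct",
                 list(window = baseline_window))
}

# per-trial baseline correction applied on the continuous recording:
# for each trial, subtract from its whole segment the per-channel mean of
# the pre-Go-Cue baseline window. Keeps the Table-1 step order while the
# data are still continuous.
baseline_correct_continuous <- function(rec, baseline_window = c(-2, 0)) {
  trial_len <- if (nrow(rec$events) > 1)
    diff(rec$events$cue_sample[1:2]) else
    ncol(rec$data) - rec$events$cue_sample[1] + 1L
  target <- which(rec$ch_types != "eog")
  for (tr in seq_len(nrow(rec$events))) {
    go <- rec$events$go_sample[tr]
    b0 <- go + round(baseline_window[1] * rec$fs)
    b1 <- go + round(baseline_window[2] * rec$fs) - 1L
    seg <- rec$events$cue_sample[tr] + seq_len(trial_len) - 1L
    seg <- seg[seg <= ncol(rec$data)]
    mu <- rowMeans(rec$data[target, b0:b1, drop = FALSE])
    rec$data[target, seg] <- rec$data[target, seg] - mu
  }
  rec
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across EEG channels at every sample so
#' that the cross-channel mean is identically zero. Idempotent.
#'
#' @param x an `eeg_epochs` (trials x channels x time) or `eeg_recording`
#'   (EEG channels only are re-referenced).
#' @return Same class as `x`.
#' @export
common_average_reference <- function(x) UseMethod("common_average_reference")

#' @export
common_average_reference.eeg_epochs <- function(x) {
  if (dim(x$data)[2] < 2) stop("common average reference needs >= 2 channels")
  m <- apply(x$data, c(1, 3), mean)             # trials x time
  x$data <- sweep(x$data, c(1, 3), m)
  add_provenance(x, "common_average_reference")
}

#' @export
common_average_reference.eeg_recording <- function(x) {
  idx <- eeg_channels(x)
  if (length(idx) < 2) stop("common average reference needs >= 2 channels")
  m <- colMeans(x$data[idx, , drop = FALSE])
  x$data[idx, ] <- sweep(x$data[idx, , drop = FALSE], 2, m)
  x
}

#' Band-pass filter a signal
#'
#' Two dialects: `"fft"` zeroes every Fourier bin whose frequency lies
#' strictly outside `[band[1], band[2]]` (the decoding path), and
#' `"butterworth"` applies a 4th-order Butterworth band-pass forward and
#' backward (zero phase, the waveform path).
#'
#' @param x numeric vector, or matrix with one channel per row.
#' @param band `c(low, high)` in Hz, `0 < low < high < fs/2`.
#' @param fs sampling rate in Hz.
#' @param kind `"fft"` or `"butterworth"`.
#' @return Filtered object of the same shape.
#' @export
bandpass <- function(x, band, fs, kind = c("fft", "butterworth")) {
  kind <- match.arg(kind)
  if (!(band[1] > 0 && band[1] < band[2]))
    stop("band must satisfy 0 < low < high")
  if (band[2] >= fs / 2) stop("band high edge must be below Nyquist (fs/2)")
  if (is.matrix(x)) {
    out <- t(apply(x, 1, bandpass, band = band, fs = fs, kind = kind))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  if (kind == "fft") {
    n <- length(x)
    f <- (seq_len(n) - 1) / n * fs
    f <- pmin(f, fs - f)                        # two-sided frequency axis
    mask <- f >= band[1] & f <= band[2]
    Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
  } else {
    flt <- signal::butter(4, band / (fs / 2), "pass")
    pad_filtfilt(flt, x)
  }
}

bandpass_epochs <- function(epochs, band, kind = "fft") {
  d <- dim(epochs$data)
  for (tr in seq_len(d[1]))
    epochs$data[tr, , ] <- bandpass(epochs$data[tr, , , drop = TRUE],
                                    band, epochs$fs, kind)
  add_provenance(epochs, "bandpass", list(band = band, kind = kind))
}

bandpass_recording <- function(rec, band, kind = "fft") {
  idx <- which(rec$ch_types != "eog")
  rec$data[idx, ] <- bandpass(rec$data[idx, , drop = FALSE],
                              band, rec$fs, kind)
  rec
}

#' Reject ocular components by ICA
#'
#' Decomposes the EEG channels of a continuous recording with FastICA
#' (as many components as channels, seeded), computes the Pearson
#' correlation of every component time course with every EOG channel over
#' the full recording, zeroes each component whose maximum absolute
#' correlation strictly exceeds `threshold`, and back-projects the rest.
#' EOG and reference channels are never altered.
#'
#' @param rec an `eeg_recording` containing EOG channels.
#' @param threshold correlation criterion in `[0, 1]` (default 0.4).
#' @param seed RNG seed for the FastICA initialization.
#' @param on_nonconvergence `"use"` (default) to proceed with the last
#'   iterate after a diagnostic warning — the symmetric-FastICA stopping
#'   rule requires every direction to stabilize, which near-Gaussian EEG
#'   background components rarely do while the artifact components
#'   stabilize within a few dozen sweeps; `"error"` to fail instead;
#'   `"pass"` to return the input unmodified.
#' @param maxit,tol FastICA iteration controls.
#' @param fit_max_samples at most this many (evenly spaced) samples are
#'   used to estimate the unmixing matrix; the component time courses,
#'   correlations and back-projection always use the full recording.
#' @return List with `recording` (cleaned), `rejected` (component indices),
#'   and `component_corr` (components x EOG-channel correlation matrix).
#' @export
ica_eog_reject <- function(rec, threshold = 0.4, seed = 42,
                           on_nonconvergence = c("use", "error", "pass"),
                           maxit = 100, tol = 1e-4,
                           fit_max_samples = 50000) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  eeg <- eeg_channels(rec)
  eog <- eog_channels(rec)
  if (length(eeg) < 2) stop("need at least 2 EEG channels for ICA")
  if (!length(eog)) stop("no EOG channels present in the recording")

  X <- t(rec$data[eeg, , drop = FALSE])          # samples x channels
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  # numerical rank of the channel covariance (the common average
  # reference removes one dimension); degenerate whitened dimensions
  # would otherwise destabilize the decomposition
  ev <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE,
              only.values = TRUE)$values
  nc <- max(1L, sum(ev > max(ev) * 1e-8))
  step <- max(1L, ceiling(nrow(Xc) / fit_max_samples))
  fit_rows <- seq(1L, nrow(Xc), by = step)
  dec <- withr::with_seed(seed,
    suppressWarnings(ica::icafast(Xc[fit_rows, , drop = FALSE], nc = nc,
                                  maxit = maxit, tol = tol)))
  if (!isTRUE(dec$converged)) {
    msg <- sprintf(
      "FastICA stopping rule not met after %d iterations (tol %g, nc %d)",
      maxit, tol, nc)
    if (on_nonconvergence == "error") stop(msg)
    if (on_nonconvergence == "pass") {
      warning(msg, "; returning input unmodified")
      return(list(recording = rec, rejected = integer(0),
                  component_corr = NULL))
    }
    warning(msg, "; using last iterate")
  }

  S <- Xc %*% t(dec$W)                           # full-length components
  comp_corr <- stats::cor(S, t(rec$data[eog, , drop = FALSE]))
  rejected <- which(apply(abs(comp_corr), 1, max) > threshold)
  keep <- setdiff(seq_len(ncol(S)), rejected)
  Xclean <- tcrossprod(S[, keep, drop = FALSE], dec$M[, keep, drop = FALSE])
  rec$data[eeg, ] <- t(sweep(Xclean, 2, center, `+`))
  list(recording = rec, rejected = rejected, component_corr = comp_corr)
}

#' Weighted average filter at Cz
#'
#' Removes the spatial common background from the vertex channel by
#' subtracting a weighted combination of the other channels:
#' `Cz := Cz - sum(w_i * channel_i)`. Weights must sum to 1.
#'
#' @param epochs an `eeg_epochs`.
#' @param weights named vector over the non-Cz channels summing to 1; by
#'   default computed by [waf_default_weights()].
#' @param cz label of the vertex channel (default "Cz").
#' @return Filtered `eeg_epochs`.
#' @export
weighted_average_filter_cz <- function(epochs, weights = NULL, cz = "Cz") {
  ci <- channel_index(epochs, cz)
  others <- setdiff(seq_along(epochs$ch_names), ci)
  if (is.null(weights)) weights <- waf_default_weights(epochs, cz = cz)
  if (is.null(names(weights)) ||
      !setequal(names(weights), epochs$ch_names[others]))
    stop("weights must be named over all non-", cz, " channels")
  if (abs(sum(weights) - 1) > 1e-6)
    stop("weights must sum to 1 (got ", signif(sum(weights), 6), ")")
  w <- weights[epochs$ch_names[others]]
  background <- apply(
    sweep(epochs$data[, others, , drop = FALSE], 2, w, `*`),
    c(1, 3), sum)
  czmat <- matrix(epochs$data[, ci, ], nrow = dim(epochs$data)[1])
  epochs$data[, ci, ] <- czmat - background
  add_provenance(epochs, "weighted_average_filter_cz",
                 list(weights = unname(w)))
}

#' Default weights for the Cz weighted average filter
#'
#' Baseline-period correlation of each non-Cz channel with Cz (pooled over
#' trials), floored at zero, shrunk toward uniform and normalized to sum 1.
#' The shrinkage keeps the weights well-defined when baseline correlations
#' are near zero.
#'
#' @param epochs an `eeg_epochs`.
#' @param baseline seconds relative to the Go-Cue.
#' @param cz vertex channel label.
#' @param shrink uniform shrinkage constant added to each floored
#'   correlation before normalization.
#' @return Named weight vector over the non-Cz channels, summing to 1.
#' @export
waf_default_weights <- function(epochs, baseline = c(-2, 0), cz = "Cz",
                                shrink = 0.25) {
  ci <- channel_index(epochs, cz)
  others <- setdiff(seq_along(epochs$ch_names), ci)
  sel <- epochs$times >= baseline[1] & epochs$times < baseline[2]
  if (!any(sel)) sel <- rep(TRUE, length(epochs$times))  # no baseline in axis
  czv <- as.vector(epochs$data[, ci, sel])
  r <- vapply(others, function(j)
    stats::cor(as.vector(epochs$data[, j, sel]), czv), numeric(1))
  w <- pmax(r, 0) + shrink
  w <- w / sum(w)
  names(w) <- epochs$ch_names[others]
  w
}

#' Z-score normalization of epochs
#'
#' Per trial and channel: subtract the mean and divide by the population
#' standard deviation (divisor `n`), making every channel of every trial
#' zero-mean, unit-sd, and the downstream features invariant to per-trial
#' affine amplitude changes.
#'
#' @param epochs an `eeg_epochs`.
#' @return Normalized `eeg_epochs`.
#' @export
zscore_epochs <- function(epochs) {
  d <- dim(epochs$data)
  mu <- apply(epochs$data, c(1, 2), mean)
  sigma <- sqrt(apply(epochs$data, c(1, 2), function(v)
    mean((v - mean(v))^2)))
  if (any(sigma == 0)) {
    bad <- which(sigma == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("zero variance in trial %d, channel %s",
                 bad[1], epochs$ch_names[bad[2]]))
  }
  epochs$data <- (epochs$data - as.vector(mu)) / as.vector(sigma)
  add_provenance(epochs, "zscore")
}

#' Extract epochs around the Go-Cue
#'
#' Cuts a fixed window relative to every Go-Cue marker using the half-open
#' convention `[start, end)`: the epoch has `round(length * fs)` samples
#' and, for a window starting at 0, its first sample is the Go-Cue sample.
#'
#' @param rec an `eeg_recording`.
#' @param window `c(start, end)` in seconds relative to the Go-Cue.
#' @param channels channels to keep (default: EEG channels).
#' @return An `eeg_epochs` with the trial labels attached.
#' @export
extract_epochs <- function(rec, window = c(0, 1), channels = NULL) {
  if (is.null(channels)) channels <- rec$ch_names[eeg_channels(rec)]
  ci <- match(channels, rec$ch_names)
  if (anyNA(ci)) stop("unknown channel(s): ",
                      paste(channels[is.na(ci)], collapse = ", "))
  T_len <- round((window[2] - window[1]) * rec$fs)
  starts <- rec$events$go_sample + round(window[1] * rec$fs)
  bad <- which(starts < 1 | starts + T_len - 1 > ncol(rec$data))
  if (length(bad))
    stop("epoch window exceeds recording bounds for trial(s): ",
         paste(bad, collapse = ", "))
  n_tr <- nrow(rec$events)
  out <- array(0, dim = c(n_tr, length(ci), T_len))
  for (tr in seq_len(n_tr))
    out[tr, , ] <- rec$data[ci, starts[tr] + seq_len(T_len) - 1L]
  times <- window[1] + (seq_len(T_len) - 1) / rec$fs
  new_epochs(out, rec$fs, channels, times,
             rec$events[, c("primary", "opposite"), drop = FALSE],
             provenance = list(list(step = "extract_epochs",
                                    window = window)))
}
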