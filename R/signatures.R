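#' Grand-average movement-related potential
#'
#' Averages the selected trials at one channel and quantifies the
#' post-Go-Cue deflections of the mean waveform: the early positive peak
#' (maximum) and the later negative extremum (minimum), whose latency
#' coincides with actual movement onset.
#'
#' @param epochs an `eeg_epochs`; for waveform summaries use a wide window
#'   (e.g. `[-1.5, 1.5]` s) extracted from band-passed data.
#' @param condition named list of label filters, e.g.
#'   `list(primary = "L")`; NULL averages all trials.
#' @param channel channel to summarize (default "Cz").
#' @return An object of class `mrcp_summary`: `waveform`, `times`,
#'   `neg_peak`, `neg_latency`, `pos_peak`, `pos_latency`, `n_trials`.
#' @export
grand_average_mrcp <- function(epochs, condition = NULL, channel = "Cz") {
  keep <- rep(TRUE, nrow(epochs$labels))
  for (nm in names(condition))
    keep <- keep & epochs$labels[[nm]] %in% condition[[nm]]
  if (!any(keep)) stop("no trials match the requested condition")
  ci <- channel_index(epochs, channel)
  wav <- colMeans(matrix(epochs$data[keep, ci, ], nrow = sum(keep)))
  post <- which(epochs$times >= 0)
  if (!length(post)) stop("epoch window contains no post-Go-Cue samples")
  ineg <- post[which.min(wav[post])]
  ipos <- post[which.max(wav[post])]
  structure(list(waveform = wav, times = epochs$times,
                 neg_peak = wav[ineg], neg_latency = epochs$times[ineg],
                 pos_peak = wav[ipos], pos_latency = epochs$times[ipos],
                 channel = channel, n_trials = sum(keep)),
            class = "mrcp_summary")
}

#' @export
print.mrcp_summary <- function(x, ...) {
  cat(sprintf(
    "<mrcp_summary> %s, %d trials: neg %.4f uV @ %.3f s, pos %.4f uV @ %.3f s\n",
    x$channel, x$n_trials, x$neg_peak, x$neg_latency, x$pos_peak,
    x$pos_latency))
  invisible(x)
}

# complex Morlet kernel, unit total energy
morlet_kernel <- function(freq, fs, n_cycles) {
  sigma_t <- n_cycles / (2 * pi * freq)
  t <- seq(-3.5 * sigma_t, 3.5 * sigma_t, by = 1 / fs)
  k <- exp(2i * pi * freq * t) * exp(-t^2 / (2 * sigma_t^2))
  k / sqrt(sum(Mod(k)^2))
}

#' Time-frequency power at one channel
#'
#' Per-trial Morlet wavelet power averaged over trials, optionally
#' baseline-normalized in decibels against the mean power in a pre-cue
#' reference interval.
#'
#' @param epochs an `eeg_epochs` covering the analysis window.
#' @param channel channel label (default "Cz").
#' @param freqs analysis frequencies in Hz (default 0.5 to 16 in 0.5-Hz
#'   steps); all must be below Nyquist.
#' @param n_cycles Morlet cycles (default 7).
#' @param normalize `"db"` (10*log10 ratio to the baseline mean per
#'   frequency) or `"none"` (raw average power).
#' @param baseline reference interval in seconds for `"db"` scaling.
#' @return List of class `tf_power`: `power` (freqs x time), `freqs`,
#'   `times`.
#' @export
time_frequency <- function(epochs, channel = "Cz",
                           freqs = seq(0.5, 16, by = 0.5), n_cycles = 7,
                           normalize = c("db", "none"),
                           baseline = c(-1.5, -0.5)) {
  normalize <- match.arg(normalize)
  if (any(freqs >= epochs$fs / 2))
    stop("analysis frequencies must be below Nyquist (fs/2)")
  ci <- channel_index(epochs, channel)
  d <- dim(epochs$data)
  n_t <- d[3]
  # centered ("same") linear convolution of x with a kernel k
  conv_same <- function(x, k) {
    half <- (length(k) - 1L) %/% 2L
    stats::convolve(x, rev(k), type = "open")[half + seq_along(x)]
  }
  pow <- matrix(0, nrow = length(freqs), ncol = n_t)
  for (fi in seq_along(freqs)) {
    k <- morlet_kernel(freqs[fi], epochs$fs, n_cycles)
    for (tr in seq_len(d[1])) {
      x <- epochs$data[tr, ci, ]
      mid <- conv_same(x, Re(k)) + 1i * conv_same(x, Im(k))
      pow[fi, ] <- pow[fi, ] + Mod(mid)^2
    }
  }
  pow <- pow / d[1]
  if (normalize == "db") {
    sel <- epochs$times >= baseline[1] & epochs$times < baseline[2]
    if (!any(sel)) stop("baseline interval outside the epoch window")
    ref <- rowMeans(pow[, sel, drop = FALSE])
    pow <- 10 * log10(sweep(pow, 1, pmax(ref, .Machine$double.xmin), "/"))
  }
  structure(list(power = pow, freqs = freqs, times = epochs$times,
                 channel = channel, normalize = normalize),
            class = "tf_power")
}

#' Scalp potential snapshots
#'
#' Mean potential per channel (over the selected trials) at each requested
#' latency, taken at the nearest sample. The value table behind a
#' topographic map sequence.
#'
#' @param epochs an `eeg_epochs`.
#' @param times latencies in seconds relative to the Go-Cue; all must lie
#'   within the epoch window.
#' @param condition named list of label filters (as in
#'   [grand_average_mrcp()]).
#' @return channels x times matrix of mean potentials (microvolts).
#' @export
scalp_snapshot <- function(epochs,
                           times = c(-1.0, -0.5, 0, 0.5, 1.0, 1.5),
                           condition = NULL) {
  rng <- range(epochs$times)
  # the half-open epoch convention drops the endpoint sample; accept
  # requests within one sample period of the axis
  tol <- 1 / epochs$fs
  bad <- times < rng[1] - tol | times > rng[2] + tol
  if (any(bad))
    stop("requested time(s) outside the epoch window: ",
         paste(times[bad], collapse = ", "))
  keep <- rep(TRUE, nrow(epochs$labels))
  for (nm in names(condition))
    keep <- keep & epochs$labels[[nm]] %in% condition[[nm]]
  if (!any(keep)) stop("no trials match the requested condition")
  avg <- apply(epochs$data[keep, , , drop = FALSE], c(2, 3), mean)
  idx <- vapply(times, function(t) which.min(abs(epochs$times - t)),
                integer(1))
  out <- avg[, idx, drop = FALSE]
  dimnames(out) <- list(epochs$ch_names, sprintf("%g", times))
  out
}
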