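#' Specification of a synthetic bimanual center-out EEG session
#'
#' Parameters of the simulated paradigm: each 11-s trial starts with a
#' direction cue at 0 s, the Go-Cue at 4 s, and actual movement onset at
#' 4.5 s. The primary (right) hand moves left/right ("L"/"R") while the
#' opposite (left) hand moves forward/backward ("F"/"B"); every one of the
#' four label combinations occurs `n_trials_per_condition` times.
#'
#' Each trial at each scalp channel is the sum of
#' * a movement-related potential template (see [mrcp_template()]) whose
#'   negative extremum at Cz is `peak_neg_L` or `peak_neg_R`,
#' * a primary-direction-dependent AR(2) process whose resonance frequency
#'   differs between L and R in proportion to `dynamics_separation`
#'   (sd `2 * noise_sd` at Cz) — the non-linear-dynamics information the
#'   reservoir features are designed to pick up,
#' * a weaker AR(2) process whose resonance depends on the opposite-hand
#'   label (sd `noise_sd` at Cz),
#' * white broadband noise (sd `noise_sd`), and
#' * ocular contamination from Poisson-timed blinks mixed through a fixed
#'   frontal mixing vector (see [generate_eog()]).
#'
#' @param n_channels number of scalp channels (montage prefix), default 24.
#' @param n_eog number of EOG reference channels, default 2.
#' @param fs sampling rate in Hz, default 1000.
#' @param n_trials_per_condition trials per (primary, opposite) label
#'   combination, default 80.
#' @param peak_neg_L,peak_neg_R negative extremum of the movement-related
#'   potential at Cz (microvolts, must be negative) for leftward and
#'   rightward primary-hand movement.
#' @param pos_peak_amp amplitude of the early positive deflection at Cz
#'   (microvolts).
#' @param pos_peak_latency,neg_peak_latency peak latencies in seconds
#'   after the Go-Cue.
#' @param dynamics_separation in `[0, 1]`; 0 makes the L and R autoregressive
#'   dynamics identical (chance-level decodable from dynamics), 1 gives the
#'   full resonance separation.
#' @param noise_sd broadband noise sd in microvolts; the AR components scale
#'   with it (so `noise_sd = 0` yields noiseless template trials).
#' @param eog_rate blink rate in blinks per second.
#' @param seed integer RNG seed; identical specs produce identical sessions.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_channels = 24, n_eog = 2, fs = 1000,
                           n_trials_per_condition = 80,
                           peak_neg_L = -10.4324, peak_neg_R = -9.4153,
                           pos_peak_amp = 3,
                           pos_peak_latency = 0.3, neg_peak_latency = 0.5,
                           dynamics_separation = 1,
                           noise_sd = 2, eog_rate = 0.2, seed = 1) {
  stopifnot(n_trials_per_condition > 0, fs > 0,
            n_channels >= 1, n_channels <= length(default_montage()),
            n_eog >= 0, noise_sd >= 0, eog_rate >= 0)
  if (dynamics_separation < 0 || dynamics_separation > 1)
    stop("dynamics_separation must lie in [0, 1]")
  if (peak_neg_L >= 0 || peak_neg_R >= 0)
    stop("peak_neg_L and peak_neg_R must be negative (negative shift)")
  structure(list(
    n_channels = n_channels, n_eog = n_eog, fs = fs,
    n_trials_per_condition = n_trials_per_condition,
    peak_neg_L = peak_neg_L, peak_neg_R = peak_neg_R,
    pos_peak_amp = pos_peak_amp,
    pos_peak_latency = pos_peak_latency,
    neg_peak_latency = neg_peak_latency,
    dynamics_separation = dynamics_separation,
    noise_sd = noise_sd, eog_rate = eog_rate, seed = as.integer(seed),
    # fixed paradigm timeline (s): cue, Go-Cue, movement onset, trial end
    cue_time = 0, go_time = 4, onset_time = 4.5, trial_len = 11),
    class = "synthetic_spec")
}

# raised-cosine bump: amp at center, compact support of given full width
hann_bump <- function(t, center, width, amp) {
  out <- numeric(length(t))
  inside <- abs(t - center) <= width / 2
  out[inside] <- amp * 0.5 * (1 + cos(2 * pi * (t[inside] - center) / width))
  out
}

#' Movement-related potential template
#'
#' Deterministic single-trial waveform over the full 11-s trial: exactly
#' zero up to the Go-Cue, a positive raised-cosine deflection peaking at
#' `pos_peak_latency` (0.3 s) and a larger negative deflection peaking at
#' `neg_peak_latency` (0.5 s, the actual movement onset). At Cz the
#' negative extremum equals `peak_neg_L` or `peak_neg_R` exactly; at other
#' channels the waveform is scaled by the central-maximum spatial profile
#' ([spatial_profile()]). Compact raised-cosine support keeps the extremum
#' exactly at the nominal latency and the template's power essentially
#' confined below 4 Hz.
#'
#' @param direction "L" or "R" (primary-hand movement direction).
#' @param spec a [synthetic_spec()].
#' @param channel channel label.
#' @return Numeric waveform (microvolts) of length `trial_len * fs`, with
#'   attribute `"time"` giving seconds relative to the Go-Cue.
#' @export
mrcp_template <- function(direction = c("L", "R"), spec = synthetic_spec(),
                          channel = "Cz") {
  direction <- match.arg(direction)
  gain <- spatial_profile(default_montage()[seq_len(spec$n_channels)])[channel]
  if (is.na(gain)) stop("unknown channel label: ", channel)
  n <- round(spec$trial_len * spec$fs)
  t_rel <- (seq_len(n) - 1) / spec$fs - spec$go_time
  peak <- if (direction == "L") spec$peak_neg_L else spec$peak_neg_R
  w <- hann_bump(t_rel, spec$pos_peak_latency, 0.25, spec$pos_peak_amp) +
    hann_bump(t_rel, spec$neg_peak_latency, 0.36, peak)
  w <- w * unname(gain)
  attr(w, "time") <- t_rel
  w
}

# AR(2) coefficients for a resonance at f0 Hz with bandwidth bw Hz
ar2_coef <- function(f0, fs, bw = 0.8) {
  r <- exp(-pi * bw / fs)
  theta <- 2 * pi * f0 / fs
  c(2 * r * cos(theta), -r^2)
}

# zero-mean AR(2) series of length n scaled to sd `sdev`
ar2_series <- function(n, coef, sdev) {
  if (sdev <= 0) return(numeric(n))
  x <- as.numeric(stats::filter(stats::rnorm(n), coef, method = "recursive"))
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x * (sdev / s)
}

# primary / opposite resonance frequencies (Hz), all inside the < 4 Hz band;
# the primary-direction contrast scales with dynamics_separation
primary_f0 <- function(direction, sep) {
  if (direction == "L") 0.8 else 0.8 + 2.6 * sep
}
opposite_f0 <- function(direction) if (direction == "F") 1.9 else 2.4

#' Generate blink artifacts and their scalp contamination
#'
#' Blinks occur at Poisson times with rate `eog_rate`; each blink is a
#' 200-ms raised-cosine transient of about 100 microvolts (amplitude
#' jittered by 10%). The blink source is mixed into the scalp channels
#' through the fixed frontal mixing vector [eog_mixing_vector()], which is
#' returned as ground truth for artifact-rejection tests.
#'
#' @param spec a [synthetic_spec()].
#' @param duration_s duration of the generated stretch in seconds.
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return List with `eog` (n_eog x samples matrix: blink source at the EOG
#'   electrodes plus sensor noise), `source` (the clean blink time course),
#'   `mixing` (named gains into scalp channels) and `contamination`
#'   (channels x samples matrix actually added to the EEG).
#' @export
generate_eog <- function(spec = synthetic_spec(), duration_s,
                         seed = spec$seed) {
  n <- round(duration_s * spec$fs)
  ch <- default_montage()[seq_len(spec$n_channels)]
  mixing <- eog_mixing_vector(ch)
  source <- numeric(n)
  withr::with_seed(seed, {
    n_blinks <- if (spec$eog_rate > 0)
      stats::rpois(1, spec$eog_rate * duration_s) else 0L
    if (n_blinks > 0) {
      centers <- stats::runif(n_blinks, 0, duration_s)
      amps <- 100 * stats::runif(n_blinks, 0.9, 1.1)
      t <- (seq_len(n) - 1) / spec$fs
      for (b in seq_len(n_blinks))
        source <- source + hann_bump(t, centers[b], 0.2, amps[b])
    }
    eog_gain <- c(1, 0.9, 0.8)[seq_len(spec$n_eog)]
    eog <- outer(eog_gain, source) +
      matrix(stats::rnorm(spec$n_eog * n, sd = spec$noise_sd),
             nrow = spec$n_eog)
  })
  contamination <- outer(unname(mixing), source)
  rownames(contamination) <- ch
  if (spec$n_eog > 0)
    rownames(eog) <- paste0("EOG", seq_len(spec$n_eog))
  list(eog = eog, source = source, mixing = mixing,
       contamination = contamination)
}

#' Generate a full synthetic session
#'
#' Lays `4 * n_trials_per_condition` trials end to end on the paradigm
#' timeline (cue 0 s, Go-Cue 4 s, movement onset 4.5 s, trial end 11 s) in
#' randomized condition order, adds the class-dependent AR(2) dynamics,
#' broadband noise, two mastoid-proxy reference channels ("M1", "M2") and
#' blink-contaminated frontal channels plus EOG electrodes. The same spec
#' (including seed) always produces a byte-identical session.
#'
#' @param spec a [synthetic_spec()].
#' @return An [new_recording()] object; `$events` carries per-trial labels
#'   and marker samples; `$meta` stores the blink `source` vector and
#'   `mixing` ground truth and the generating spec.
#' @export
generate_session <- function(spec = synthetic_spec()) {
  fs <- spec$fs
  trial_n <- round(spec$trial_len * fs)
  n_trials <- 4L * spec$n_trials_per_condition
  total_n <- trial_n * n_trials
  ch <- default_montage()[seq_len(spec$n_channels)]
  gain <- unname(spatial_profile(ch))

  conditions <- expand.grid(primary = c("L", "R"), opposite = c("F", "B"),
                            stringsAsFactors = FALSE)
  labels <- conditions[rep(seq_len(4), each = spec$n_trials_per_condition), ]

  templates <- list(L = vapply(ch, function(cc)
                      as.numeric(mrcp_template("L", spec, cc)), numeric(trial_n)),
                    R = vapply(ch, function(cc)
                      as.numeric(mrcp_template("R", spec, cc)), numeric(trial_n)))

  data <- matrix(0, nrow = spec$n_channels + 2 + spec$n_eog, ncol = total_n)
  rownames(data) <- c(ch, "M1", "M2",
                      if (spec$n_eog > 0) paste0("EOG", seq_len(spec$n_eog)))
  ch_types <- c(rep("eeg", spec$n_channels), rep("ref", 2),
                rep("eog", spec$n_eog))

  withr::with_seed(spec$seed, {
    ord <- sample.int(n_trials)
    labels <- labels[ord, , drop = FALSE]
    rownames(labels) <- NULL
    ar_sd <- 2 * spec$noise_sd
    opp_sd <- spec$noise_sd
    for (tr in seq_len(n_trials)) {
      cols <- (tr - 1L) * trial_n + seq_len(trial_n)
      prim <- labels$primary[tr]
      opp <- labels$opposite[tr]
      cf_p <- ar2_coef(primary_f0(prim, spec$dynamics_separation), fs,
                       bw = 0.3)
      cf_o <- ar2_coef(opposite_f0(opp), fs, bw = 0.6)
      seg <- t(templates[[prim]])           # channels x time
      for (c_i in seq_len(spec$n_channels)) {
        seg[c_i, ] <- seg[c_i, ] +
          gain[c_i] * (ar2_series(trial_n, cf_p, ar_sd) +
                       ar2_series(trial_n, cf_o, opp_sd))
      }
      if (spec$noise_sd > 0) {
        seg <- seg + matrix(stats::rnorm(length(seg), sd = spec$noise_sd),
                            nrow = spec$n_channels)
        data[spec$n_channels + 1:2, cols] <-
          matrix(stats::rnorm(2 * trial_n, sd = 0.5 * spec$noise_sd), 2)
      }
      data[seq_len(spec$n_channels), cols] <- seg
    }
  })

  eogen <- generate_eog(spec, duration_s = total_n / fs,
                        seed = spec$seed + 1L)
  data[seq_len(spec$n_channels), ] <-
    data[seq_len(spec$n_channels), ] + eogen$contamination
  if (spec$n_eog > 0)
    data[spec$n_channels + 2 + seq_len(spec$n_eog), ] <- eogen$eog

  starts <- (seq_len(n_trials) - 1L) * trial_n + 1L
  events <- data.frame(
    trial = seq_len(n_trials),
    cue_sample = starts,
    go_sample = starts + round(spec$go_time * fs),
    onset_sample = starts + round(spec$onset_time * fs),
    primary = labels$primary, opposite = labels$opposite,
    stringsAsFactors = FALSE)

  new_recording(data, fs, ch_types, events,
                meta = list(spec = spec, eog_source = eogen$source,
                            eog_mixing = eogen$mixing))
}
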