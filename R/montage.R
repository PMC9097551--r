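#' Default 24-channel montage
#'
#' Electrode labels (10-20 system) covering frontal, central, parietal,
#' temporal and occipital regions, ordered with the vertex electrode Cz
#' first. This is the montage assumed by the synthetic generator and by
#' the scalp-topography summaries.
#'
#' @return Character vector of 24 channel labels.
#' @export
default_montage <- function() {
  c("Cz", "C1", "C2", "C3", "C4",
    "Fz", "F3", "F4", "FCz", "FC3", "FC4",
    "CP3", "CP4",
    "Oz", "O1", "O2",
    "T7", "T8",
    "POz", "Pz", "P3", "P4", "P7", "P8")
}

#' Spatial amplitude profile of the movement-related potential
#'
#' Scalp gain of the slow movement-related deflection for each channel:
#' unity at Cz (central maximum) and decaying with squared channel-index
#' distance in the montage order. Strictly decreasing away from Cz so the
#' vertex is always the unique extremum in topography tests.
#'
#' @param ch_names channel labels; must be a subset of [default_montage()].
#' @param decay index-distance scale of the squared-exponential decay.
#' @return Named numeric vector of gains in (0, 1].
#' @export
spatial_profile <- function(ch_names = default_montage(), decay = 12) {
  montage <- default_montage()
  idx <- match(ch_names, montage)
  if (anyNA(idx)) {
    stop("unknown channel label(s): ",
         paste(ch_names[is.na(idx)], collapse = ", "))
  }
  g <- exp(-((idx - 1) / decay)^2)
  names(g) <- ch_names
  g
}

#' Ocular contamination mixing vector
#'
#' Fixed forward-mixing gains of the blink source into each scalp channel:
#' strong frontally, weak posteriorly. Used by the synthetic generator and
#' returned as ground truth for artifact-rejection tests.
#'
#' @param ch_names channel labels.
#' @return Named numeric vector of mixing gains.
#' @export
eog_mixing_vector <- function(ch_names = default_montage()) {
  gains <- c(Cz = 0.10, C1 = 0.08, C2 = 0.08, C3 = 0.07, C4 = 0.07,
             Fz = 0.35, F3 = 0.30, F4 = 0.30, FCz = 0.28, FC3 = 0.22,
             FC4 = 0.22, CP3 = 0.04, CP4 = 0.04, Oz = 0.01, O1 = 0.01,
             O2 = 0.01, T7 = 0.03, T8 = 0.03, POz = 0.01, Pz = 0.02,
             P3 = 0.02, P4 = 0.02, P7 = 0.01, P8 = 0.01)
  missing <- setdiff(ch_names, names(gains))
  if (length(missing)) {
    stop("unknown channel label(s): ", paste(missing, collapse = ", "))
  }
  gains[ch_names]
}
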