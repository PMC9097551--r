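#' Pipeline configuration
#'
#' Bundles all stage configurations. Exactly one input source must be
#' provided: a synthetic session spec or a recording file path. The global
#' seed propagates to every stochastic stage (synthesis, ICA
#' initialization, reservoir draws, fold assignments) unless a sub-config
#' overrides it.
#'
#' @param synthetic a [synthetic_spec()], or NULL when reading a file.
#' @param input path to a recording container, or NULL.
#' @param preprocess a [preprocess_config()].
#' @param esn an [esn_config()] for a fixed-cell run, or NULL to run the
#'   mesh grid search over the default grids.
#' @param cv a [cv_spec()].
#' @param variance_target PCA cumulative explained-variance target.
#' @param paper_mode global-PCA variant flag (see [cross_validate()]).
#' @param seed global integer seed.
#' @param outdir optional output directory for report files.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, input = NULL,
                            preprocess = preprocess_config(),
                            esn = NULL, cv = NULL,
                            variance_target = 0.99, paper_mode = FALSE,
                            seed = 1, outdir = NULL) {
  if (is.null(synthetic) && is.null(input))
    stop("no input: provide a synthetic spec or a recording path")
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_spec"))
  if (!is.null(esn)) stopifnot(inherits(esn, "esn_config"))
  if (is.null(cv)) cv <- cv_spec(seed = seed)
  structure(list(synthetic = synthetic, input = input,
                 preprocess = preprocess, esn = esn, cv = cv,
                 variance_target = variance_target,
                 paper_mode = isTRUE(paper_mode),
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Preprocess a continuous recording into decoding epochs
#'
#' Applies the fixed chain in order: down-sampling, re-referencing to the
#' designated ("binaural") reference channels, per-trial baseline
#' correction, common average reference, ICA-based ocular rejection,
#' band-pass filtering, epoching around the Go-Cue, and per-trial z-score
#' normalization. The returned epochs carry a provenance record of every
#' step and its parameters.
#'
#' @param rec an `eeg_recording`.
#' @param cfg a [preprocess_config()].
#' @param ica_seed seed for the FastICA initialization.
#' @param keep_recording if TRUE, also return the cleaned continuous
#'   recording (before epoching) for signature summaries.
#' @return The z-scored decoding `eeg_epochs`; if `keep_recording`, a list
#'   with `epochs` and `recording`.
#' @export
preprocess_recording <- function(rec, cfg = preprocess_config(),
                                 ica_seed = 42, keep_recording = FALSE) {
  prov <- list()
  rec <- resample_recording(rec, cfg$target_fs)
  prov <- c(prov, list(list(step = "resample", target_fs = cfg$target_fs)))
  rec <- rereference(rec, cfg$reference_channels)
  prov <- c(prov, list(list(step = "rereference",
                            reference = cfg$reference_channels)))
  rec <- baseline_correct_continuous(rec, cfg$baseline_window)
  prov <- c(prov, list(list(step = "baseline_correct",
                            window = cfg$baseline_window)))
  if (cfg$car) {
    rec <- common_average_reference(rec)
    prov <- c(prov, list(list(step = "common_average_reference")))
  }
  ica <- ica_eog_reject(rec, threshold = cfg$ica_corr_threshold,
                        seed = ica_seed)
  rec <- ica$recording
  prov <- c(prov, list(list(step = "ica_eog_reject",
                            threshold = cfg$ica_corr_threshold,
                            rejected = ica$rejected, seed = ica_seed)))
  rec <- bandpass_recording(rec, cfg$band,
                            kind = if (cfg$filter_kind == "butterworth")
                              "butterworth" else "fft")
  prov <- c(prov, list(list(step = "bandpass", band = cfg$band,
                            kind = cfg$filter_kind)))
  epochs <- extract_epochs(rec, cfg$epoch_window)
  epochs$provenance <- c(prov, epochs$provenance)
  epochs <- zscore_epochs(epochs)
  if (keep_recording) list(epochs = epochs, recording = rec) else epochs
}

#' Neural-signature summaries of a cleaned recording
#'
#' Re-filters the cleaned continuous recording with the zero-phase
#' Butterworth variant, extracts wide epochs, baseline-corrects them,
#' applies the Cz weighted average filter, and computes grand-average
#' waveforms per primary direction, the Cz time-frequency power map and
#' scalp potential snapshots.
#'
#' @param rec a cleaned (post-ICA) `eeg_recording`, unfiltered or
#'   FFT-filtered.
#' @param band analysis band in Hz.
#' @param window wide analysis window in seconds relative to the Go-Cue
#'   (extended down to -2 s internally for baseline correction).
#' @return List with `mrcp_L`, `mrcp_R` ([grand_average_mrcp()] objects),
#'   `tf` ([time_frequency()]), `topo` ([scalp_snapshot()]).
#' @export
signature_summaries <- function(rec, band = c(0.01, 4),
                                window = c(-1.5, 1.5)) {
  rec <- bandpass_recording(rec, band, kind = "butterworth")
  wide <- extract_epochs(rec, c(-2, window[2]))
  wide <- baseline_correct(wide, c(-2, 0))
  wide <- weighted_average_filter_cz(wide)
  sel <- wide$times >= window[1]
  wide$data <- wide$data[, , sel, drop = FALSE]
  wide$times <- wide$times[sel]
  list(mrcp_L = grand_average_mrcp(wide, list(primary = "L")),
       mrcp_R = grand_average_mrcp(wide, list(primary = "R")),
       tf = time_frequency(wide),
       topo = scalp_snapshot(wide))
}

#' Run the full decoding pipeline
#'
#' Generates (or loads) a session, preprocesses it, extracts reservoir
#' readout features, and either evaluates a fixed reservoir configuration
#' or runs the mesh grid search; optionally writes CSV/JSON reports. A
#' manifest records every parameter and seed; identical configurations
#' produce identical manifest hashes and identical results.
#'
#' @param config a [pipeline_config()].
#' @param signatures also compute [signature_summaries()] (default FALSE).
#' @return An object of class `decoding_result`: `accuracy`, `per_subset`,
#'   `selected` (c, NN), `surface` (grid runs), `folds`, `manifest`,
#'   `manifest_hash`, optionally `signatures`.
#' @export
run_pipeline <- function(config, signatures = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  rec <- if (!is.null(config$synthetic)) generate_session(config$synthetic)
         else read_recording(config$input)
  pp <- preprocess_recording(rec, config$preprocess,
                             ica_seed = config$seed + 17L,
                             keep_recording = signatures)
  epochs <- if (signatures) pp$epochs else pp
  C <- dim(epochs$data)[2]

  if (!is.null(config$esn)) {
    model <- init_reservoir(config$esn, C)
    feats <- extract_features(epochs, model)
    acc <- wohm_accuracy(feats, epochs$labels, config$cv,
                         config$variance_target, config$paper_mode)
    selected <- data.frame(c = config$esn$c, NN = config$esn$NN)
    surface <- data.frame(c = config$esn$c, NN = config$esn$NN,
                          accuracy = as.numeric(acc))
    folds <- attr(acc, "folds")
  } else {
    gs <- grid_search(epochs, cv = config$cv,
                      variance_target = config$variance_target,
                      seed = config$seed, paper_mode = config$paper_mode)
    acc <- gs$accuracy
    selected <- gs$selected[, c("c", "NN")]
    surface <- gs$surface
    folds <- NULL
  }

  manifest <- list(config = config_to_list(config),
                   n_trials = dim(epochs$data)[1], n_channels = C,
                   fs = epochs$fs,
                   provenance = epochs$provenance,
                   package_version = as.character(utils::packageVersion("esndecode")))
  result <- structure(list(
    accuracy = as.numeric(acc),
    per_subset = attr(acc, "per_subset"),
    selected = selected, surface = surface, folds = folds,
    manifest = manifest, manifest_hash = manifest_hash(manifest)),
    class = "decoding_result")
  if (signatures)
    result$signatures <- signature_summaries(pp$recording,
                                             band = config$preprocess$band)
  if (!is.null(config$outdir)) write_reports(result, config$outdir)
  result
}

manifest_hash <- function(manifest) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}

write_reports <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$surface,
                   file.path(outdir, "accuracy_surface.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(result$selected, accuracy = result$accuracy),
                   file.path(outdir, "decoding_result.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(outdir)
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> W-OHM accuracy %.4f (c=%.1f, NN=%d)\n",
              x$accuracy, x$selected$c, x$selected$NN))
  if (!is.null(x$per_subset))
    cat(sprintf("  per subset: F=%.4f B=%.4f\n",
                x$per_subset["F"], x$per_subset["B"]))
  invisible(x)
}
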