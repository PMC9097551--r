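#' Write and read the package containers
#'
#' Recordings and epoch sets are serialized with R's native serialization
#' (a single hierarchical file holding signals, labels, time axes and
#' provenance); configurations are serialized as YAML. Round trips
#' preserve data bit-exactly.
#'
#' @param x an `eeg_recording` or `eeg_epochs`.
#' @param path file path.
#' @return `path`, invisibly (writers); the restored object (readers).
#' @name container_io
NULL

#' @rdname container_io
#' @export
write_recording <- function(x, path) {
  stopifnot(inherits(x, "eeg_recording"))
  saveRDS(x, path)
  invisible(path)
}

#' @rdname container_io
#' @param format container format; only the native container is supported.
#' @export
read_recording <- function(path, format = "container") {
  if (!identical(format, "container"))
    stop("unknown format: ", format, " (supported: 'container')")
  if (!file.exists(path)) stop("file does not exist: ", path)
  x <- readRDS(path)
  if (!inherits(x, "eeg_recording"))
    stop("file does not contain an eeg_recording: ", path)
  if (is.null(x$events) || !nrow(x$events))
    stop("recording has no event markers: ", path)
  x
}

#' @rdname container_io
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "eeg_epochs"))
  saveRDS(x, path)
  invisible(path)
}

#' @rdname container_io
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  x <- readRDS(path)
  if (!inherits(x, "eeg_epochs"))
    stop("file does not contain an eeg_epochs: ", path)
  x
}

config_classes <- c("synthetic_spec", "preprocess_config", "esn_config",
                    "cv_spec", "pipeline_config")

# flatten a config (possibly nested) to plain lists, tagging classes
config_to_list <- function(x) {
  out <- lapply(unclass(x), function(v)
    if (inherits(v, config_classes)) config_to_list(v) else v)
  out$.class <- class(x)[1]
  out
}

# rebuild a tagged list through the matching constructor (re-validates)
list_to_config <- function(obj) {
  cls <- obj$.class
  obj$.class <- NULL
  ctor <- switch(cls,
                 synthetic_spec = synthetic_spec,
                 preprocess_config = preprocess_config,
                 esn_config = esn_config,
                 cv_spec = cv_spec,
                 pipeline_config = pipeline_config,
                 stop("unknown config class: ", cls))
  obj <- lapply(obj, function(v)
    if (is.list(v) && !is.null(v$.class)) list_to_config(v) else v)
  obj[setdiff(names(obj), names(formals(ctor)))] <- NULL
  do.call(ctor, obj)
}

#' Serialize a configuration to YAML
#'
#' @param config any package config object ([synthetic_spec()],
#'   [preprocess_config()], [esn_config()], [cv_spec()],
#'   [pipeline_config()]).
#' @param path YAML file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' Restore a configuration from YAML
#'
#' @param path YAML file path.
#' @return The configuration object, rebuilt through its constructor so
#'   all invariants are re-validated.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  list_to_config(yaml::read_yaml(path))
}
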