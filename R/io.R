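#' Read and write EEG recordings as a plain-text array archive
#'
#' The archive is a directory holding `meta.json` (sampling rate, channel
#' labels, clock start) and `signals.csv` (one column per channel, one row
#' per sample, header row of channel labels). It round-trips
#' [eeg_recording()] objects exactly up to decimal-printing precision.
#' EDF input is not supported in this build; an informative error points
#' to the archive format instead.
#'
#' @param path Archive directory.
#' @param format Only `"array-archive"` is implemented.
#' @return `read_recording` returns an [eeg_recording()];
#'   `write_recording` returns `path` invisibly.
#' @export
read_recording <- function(path, format = c("array-archive", "EDF")) {
  format <- match.arg(format)
  if (format == "EDF") {
    stop(paste("EDF reading is not available in this build;",
               "export to the array-archive format instead"), call. = FALSE)
  }
  meta_path <- file.path(path, "meta.json")
  sig_path <- file.path(path, "signals.csv")
  if (!file.exists(meta_path) || !file.exists(sig_path)) {
    stop(sprintf("`%s` is not a recording archive (missing meta.json or signals.csv)",
                 path), call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$sampling_rate)) {
    stop("archive metadata is missing `sampling_rate`", call. = FALSE)
  }
  sig <- utils::read.csv(sig_path, check.names = FALSE)
  if (nrow(sig) == 0L) stop("empty signal file", call. = FALSE)
  eeg_recording(
    samples = t(as.matrix(sig)),
    sampling_rate = meta$sampling_rate,
    channel_labels = meta$channel_labels %||% colnames(sig),
    start_clock_s = meta$start_clock_s %||% 0
  )
}

#' @rdname read_recording
#' @param recording An [eeg_recording()].
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(sampling_rate = recording$sampling_rate,
         channel_labels = recording$channel_labels,
         start_clock_s = recording$start_clock_s),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA
  )
  sig <- as.data.frame(t(recording$samples))
  names(sig) <- recording$channel_labels
  utils::write.csv(sig, file.path(path, "signals.csv"), row.names = FALSE)
  invisible(path)
}

#' Read and write seizure annotations as CSV
#'
#' Columns: `onset_s`, `offset_s`, and optionally `clock_hour` and
#' `patient`.
#'
#' @param path CSV file path.
#' @return `read_annotations` returns a [seizure_annotation()] table.
#' @export
read_annotations <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("onset_s", "offset_s") %in% names(d))) {
    stop("annotation CSV needs columns onset_s, offset_s", call. = FALSE)
  }
  ann <- seizure_annotation(d$onset_s, d$offset_s)
  for (extra in intersect(c("clock_hour", "patient"), names(d))) {
    ann[[extra]] <- d[[extra]]
  }
  ann
}

#' @rdname read_annotations
#' @param annotations A [seizure_annotation()] table.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(as.data.frame(annotations), path, row.names = FALSE)
  invisible(path)
}

#' Save / load a trained model as JSON
#'
#' Serialises the architecture description, the per-layer posterior
#' parameters (`mu`, `rho` for weights and biases), the input transform,
#' and any stored auxiliary priors to a single JSON file. Precomputed
#' index tables are rebuilt on load.
#'
#' @param model A [train_bcnn()] model.
#' @param path File path (conventionally `.json`).
#' @return `save_bcnn` returns `path` invisibly; `load_bcnn` the restored
#'   model.
#' @export
save_bcnn <- function(model, path) {
  stopifnot(inherits(model, "bcnn_model"))
  spec <- model$spec
  layers <- lapply(model$layers, function(l) {
    list(kind = l$kind,
         mu_w = as.numeric(l$mu_w), rho_w = as.numeric(l$rho_w),
         dim_w = dim(l$mu_w),
         mu_b = as.numeric(l$mu_b), rho_b = as.numeric(l$rho_b))
  })
  priors <- if (is.null(model$priors)) NULL else {
    lapply(model$priors, function(p) {
      list(values = p$values, bandwidth = p$bandwidth, domain = p$domain)
    })
  }
  jsonlite::write_json(
    list(
      spec = list(n_channels = spec$n_channels,
                  conv_filters = spec$conv_filters,
                  dense_units = spec$dense_units,
                  input_time = spec$input_time,
                  input_freq = spec$input_freq,
                  activation_slope = spec$activation_slope),
      layers = layers,
      preproc = model$preproc,
      priors = priors,
      loss_trace = model$loss_trace,
      config = model$config
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname save_bcnn
#' @export
load_bcnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  spec <- network_spec(
    n_channels = obj$spec$n_channels,
    conv_filters = obj$spec$conv_filters,
    dense_units = obj$spec$dense_units,
    input_time = obj$spec$input_time,
    input_freq = obj$spec$input_freq,
    activation_slope = obj$spec$activation_slope %||% 0.1
  )
  layers <- lapply(obj$layers, function(l) {
    structure(
      list(kind = l$kind,
           mu_w = matrix(l$mu_w, nrow = l$dim_w[1], ncol = l$dim_w[2]),
           rho_w = matrix(l$rho_w, nrow = l$dim_w[1], ncol = l$dim_w[2]),
           mu_b = l$mu_b, rho_b = l$rho_b),
      class = "variational_layer"
    )
  })
  priors <- if (is.null(obj$priors) || length(obj$priors) == 0L) NULL else {
    lapply(obj$priors, function(p) {
      fit_auxiliary_prior(p$values, domain = p$domain, bandwidth = p$bandwidth)
    })
  }
  structure(
    list(spec = spec, layers = layers, preproc = obj$preproc,
         priors = priors, loss_trace = obj$loss_trace, config = obj$config),
    class = "bcnn_model"
  )
}
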