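#' Select high-confidence preictal predictions
#'
#' The biomarker probe only inspects segments the model is both confident
#' and positive about: uncertainty level strictly below `level_max` and
#' mean prediction score strictly above `mean_min`.
#'
#' @param predictions Data frame with columns `mean_score` and
#'   `uncertainty` (e.g. [predict.bcnn_model()] output), or a list of
#'   [uncertainty_level()] estimates.
#' @param level_max Uncertainty ceiling (strict `<`).
#' @param mean_min Mean-score floor (strict `>`).
#' @return Integer vector of selected row indices (segment ids).
#' @export
select_confident_segments <- function(predictions, level_max = 0.1,
                                      mean_min = 0.9) {
  if (is.list(predictions) && !is.data.frame(predictions) &&
      all(vapply(predictions, inherits, logical(1), "uncertainty_estimate"))) {
    predictions <- data.frame(
      mean_score = vapply(predictions, `[[`, numeric(1), "mean_score"),
      uncertainty = vapply(predictions, `[[`, numeric(1), "level")
    )
  }
  which(predictions$uncertainty < level_max & predictions$mean_score > mean_min)
}

#' Time-resolved attention profile of one feature map
#'
#' Accumulates the rectified (positive-part) activations of a first-layer
#' feature map over the kernel and frequency axes, leaving one attention
#' value per first-layer time index.
#'
#' @param feature_map Array `kernels x T1 x F1` (the `fmap1` element of
#'   [bcnn_forward()]).
#' @param normalize `"raw"` or `"max1"` (divide by the maximum when any
#'   value is positive).
#' @return Object of class `attention_profile`: numeric vector of length
#'   `T1` with attribute `normalization`.
#' @export
attention_profile <- function(feature_map, normalize = c("raw", "max1")) {
  normalize <- match.arg(normalize)
  if (length(dim(feature_map)) != 3L) {
    stop("`feature_map` must be a 3-d array (kernels x time x freq)",
         call. = FALSE)
  }
  vals <- apply(pmax(feature_map, 0), 2L, sum)
  if (normalize == "max1" && any(vals > 0)) vals <- vals / max(vals)
  structure(vals, class = "attention_profile", normalization = normalize)
}

#' Posterior-averaged attention map for a segment
#'
#' Runs `samples` forward passes of the same input, each through an
#' independent weight realisation, and averages the per-pass attention
#' profiles ([attention_profile()]) to smooth posterior noise. First-layer
#' time indices map back to input time through the stride-2 convolution:
#' with 56 input frames of ~0.536 s hop, each of the 26 attention steps
#' spans roughly 1.07 s.
#'
#' @param spec A [network_spec()].
#' @param layers Trained variational layers.
#' @param segment Preprocessed input array (`n x 56 x 128`).
#' @param samples Number of weight realisations averaged (reference
#'   protocol: 100).
#' @param seed Integer seed.
#' @param normalize Passed to [attention_profile()].
#' @return An `attention_profile` (length `T1`), averaged over
#'   realisations; normalisation is applied after averaging.
#' @export
attention_map <- function(spec, layers, segment, samples = 100L, seed = NULL,
                          normalize = c("raw", "max1")) {
  normalize <- match.arg(normalize)
  if (samples < 1L) stop("`samples` must be >= 1", call. = FALSE)
  prof <- with_seed(seed, {
    acc <- NULL
    for (s in seq_len(samples)) {
      w <- sample_weights(spec, layers)
      p <- attention_profile(bcnn_forward(spec, w, segment)$fmap1)
      acc <- if (is.null(acc)) as.numeric(p) else acc + as.numeric(p)
    }
    acc / samples
  })
  if (normalize == "max1" && any(prof > 0)) prof <- prof / max(prof)
  structure(prof, class = "attention_profile", normalization = normalize)
}
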