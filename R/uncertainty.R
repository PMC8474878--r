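#' Uncertainty level of a Monte-Carlo prediction
#'
#' The uncertainty level is the sample standard deviation of the
#' Monte-Carlo prediction scores divided by the absolute distance of their
#' mean from 0.5. The denominator targets the uniform-like case: samples
#' spread across `[0, 1]` have a mean near 0.5 and blow the level up. A
#' zero denominator yields `+Inf`; for display the level is capped at 10.
#'
#' @param samples A [mc_predict()] result (numeric vector of scores in
#'   `[0, 1]`, length >= 2).
#' @return Object of class `uncertainty_estimate`: list with `mean_score`,
#'   `std_score` (sample sd, n-1 denominator), `level`, `display_level`.
#' @export
uncertainty_level <- function(samples) {
  s <- as.numeric(samples)
  if (length(s) < 2L) stop("need at least 2 prediction samples", call. = FALSE)
  if (any(s < 0 | s > 1)) stop("scores must lie in [0, 1]", call. = FALSE)
  m <- mean(s)
  sdev <- sd(s)
  denom <- abs(m - 0.5)
  level <- if (denom > 0) sdev / denom else Inf
  structure(
    list(mean_score = m, std_score = sdev, level = level,
         display_level = min(level, 10)),
    class = "uncertainty_estimate"
  )
}

#' @export
print.uncertainty_estimate <- function(x, ...) {
  cat(sprintf("<uncertainty_estimate> mean %.3f, sd %.3f, level %s\n",
              x$mean_score, x$std_score,
              if (is.finite(x$level)) sprintf("%.3f", x$level) else "Inf"))
  invisible(x)
}

#' Classify a prediction by confidence and (optionally) correctness
#'
#' Predictions whose uncertainty level exceeds `confident_threshold` are
#' `uncertain`. Confident predictions are split into `confident_correct`
#' and `confident_wrong` by comparing the rounded mean score to the truth
#' when a truth label is available -- the confidently wrong case being the
#' clinically undesirable one -- and are otherwise reported as
#' `confident`.
#'
#' @param estimate An [uncertainty_level()] result.
#' @param truth Optional true label, 0 (interictal) or 1 (preictal).
#' @param confident_threshold Level above which a prediction counts as
#'   uncertain.
#' @return One of `"uncertain"`, `"confident"`, `"confident_correct"`,
#'   `"confident_wrong"`.
#' @export
classify_prediction <- function(estimate, truth = NULL,
                                confident_threshold = 0.1) {
  stopifnot(inherits(estimate, "uncertainty_estimate"))
  if (estimate$level > confident_threshold) return("uncertain")
  if (is.null(truth)) return("confident")
  if (round(estimate$mean_score) == truth) "confident_correct" else "confident_wrong"
}
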