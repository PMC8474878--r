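#' Area under the ROC curve over segment scores
#'
#' Rank-based (Mann--Whitney) AUC: the probability that a randomly chosen
#' positive segment scores above a randomly chosen negative one, with tied
#' scores contributing 1/2.
#'
#' @param scores Numeric risk scores.
#' @param labels Integer labels, 0 (interictal) / 1 (preictal); both
#'   classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
segment_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  }
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC requires both classes to be present", call. = FALSE)
  }
  r <- rank(scores) # average ranks handle ties as 1/2
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Uncertainty-gated, smoothed seizure-risk timeline
#'
#' Builds the retrospective risk curve used for continuous-recording
#' review: predictions whose uncertainty level exceeds the gate are
#' discarded (marked `NA`, not zero), and a backward moving average over
#' the most recent `smooth_window` retained points (fewer during warm-up)
#' smooths the surviving scores.
#'
#' @param times_s Strictly increasing prediction times in seconds.
#' @param scores Mean prediction scores aligned with `times_s`.
#' @param uncertainties Uncertainty levels aligned with `times_s`.
#' @param smooth_window Number of retained points averaged (default 50).
#' @param uncertainty_gate Maximum uncertainty level kept (default 1).
#' @return Data frame of class `risk_timeline` with columns `time_s`,
#'   `raw_score`, `uncertainty`, `retained`, `smoothed` (`NA` where
#'   gated out).
#' @export
risk_timeline <- function(times_s, scores, uncertainties,
                          smooth_window = 50L, uncertainty_gate = 1.0) {
  n <- length(times_s)
  if (length(scores) != n || length(uncertainties) != n) {
    stop("inputs must be aligned", call. = FALSE)
  }
  if (n > 1L && any(diff(times_s) <= 0)) {
    stop("`times_s` must be strictly increasing", call. = FALSE)
  }
  retained <- uncertainties <= uncertainty_gate
  smoothed <- rep(NA_real_, n)
  if (any(retained)) {
    kept <- scores[retained]
    cs <- cumsum(kept)
    k <- seq_along(kept)
    lo <- pmax(k - smooth_window + 1L, 1L)
    sm <- (cs - c(0, cs)[lo]) / (k - lo + 1L)
    smoothed[retained] <- sm
  }
  structure(
    data.frame(time_s = times_s, raw_score = scores,
               uncertainty = uncertainties, retained = retained,
               smoothed = smoothed),
    class = c("risk_timeline", "data.frame")
  )
}

#' Leakage-free train/test folds separated by ictal events
#'
#' Splits labelled segments into evaluation folds, one per inter-ictal
#' period that contains preictal data, so that the model evaluated on a
#' period never saw that period's preictal segments during training:
#' the fold's test set is all segments of its period, and its training
#' set draws preictal and interictal segments from the other periods only.
#'
#' @param meta Data frame with columns `id`, `label` (`"preictal"` /
#'   `"interictal"`), and `period` (integer period index; see
#'   [assign_periods()]).
#' @return List of folds, each a list with `test_ids`, `train_ids`,
#'   `period`.
#' @export
period_split <- function(meta) {
  need <- c("id", "label", "period")
  if (!all(need %in% names(meta))) {
    stop("`meta` must have columns id, label, period", call. = FALSE)
  }
  pre_periods <- sort(unique(meta$period[meta$label == "preictal"]))
  if (length(pre_periods) < 2L) {
    stop(paste("need at least 2 seizure-bounded periods with preictal data;",
               "a single period cannot be split without leakage"),
         call. = FALSE)
  }
  lapply(pre_periods, function(p) {
    list(
      period = p,
      test_ids = meta$id[meta$period == p],
      train_ids = meta$id[meta$period != p]
    )
  })
}

#' Assign segments to inter-ictal periods
#'
#' Period `k` covers times from leading onset `k - 1` (or the recording
#' start) up to leading onset `k`; segments after the last onset get
#' period `n + 1`. A seizure's preictal block therefore always falls in
#' the period that the seizure terminates.
#'
#' @param start_s Segment start times in seconds.
#' @param leading_onsets_s Sorted leading-seizure onset times.
#' @return Integer vector of period indices.
#' @export
assign_periods <- function(start_s, leading_onsets_s) {
  findInterval(start_s, sort(leading_onsets_s)) + 1L
}
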