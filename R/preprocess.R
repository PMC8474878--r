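#' Multichannel EEG recording container
#'
#' @param samples Numeric matrix, channels in rows, samples in columns.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param channel_labels Character vector, one label per channel.
#' @param start_clock_s Clock time of sample 1 in seconds since midnight.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, sampling_rate, channel_labels = NULL,
                          start_clock_s = 0) {
  samples <- as.matrix(samples)
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  if (nrow(samples) < 1L) stop("need at least one channel", call. = FALSE)
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("CH%02d", seq_len(nrow(samples)))
  }
  if (length(channel_labels) != nrow(samples)) {
    stop("`channel_labels` length must equal the number of channels",
         call. = FALSE)
  }
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         channel_labels = as.character(channel_labels),
         start_clock_s = start_clock_s),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f min), clock start %.2f h\n",
    nrow(x$samples), ncol(x$samples), x$sampling_rate,
    ncol(x$samples) / x$sampling_rate / 60, x$start_clock_s / 3600
  ))
  invisible(x)
}

recording_duration <- function(recording) {
  ncol(recording$samples) / recording$sampling_rate
}

#' Seizure annotation table
#'
#' @param onset_s,offset_s Numeric vectors of onset/offset times in seconds
#'   from recording start; must be sorted by onset with `onset_s < offset_s`.
#' @return Data frame of class `seizure_annotation`.
#' @export
seizure_annotation <- function(onset_s, offset_s) {
  if (length(onset_s) != length(offset_s)) {
    stop("onset and offset vectors must have equal length", call. = FALSE)
  }
  if (any(offset_s <= onset_s)) {
    stop("each `offset_s` must exceed its `onset_s`", call. = FALSE)
  }
  if (is.unsorted(onset_s)) {
    stop("annotations must be sorted by onset", call. = FALSE)
  }
  structure(
    data.frame(onset_s = as.numeric(onset_s), offset_s = as.numeric(offset_s)),
    class = c("seizure_annotation", "data.frame")
  )
}

#' Merge clustered seizures into leading seizures
#'
#' Seizures less than `gap_min` minutes (strictly) after the previous
#' seizure's onset are absorbed into it, chained left to right; the onset
#' of the leading seizure becomes the onset of the combined seizure and the
#' combined offset is the latest offset in the chain. The operation is
#' idempotent.
#'
#' @param annotations A sorted [seizure_annotation()] table.
#' @param gap_min Merging threshold in minutes (strict `<`).
#' @return A [seizure_annotation()] table of leading seizures only.
#' @export
merge_leading_seizures <- function(annotations, gap_min = 30) {
  ann <- as.data.frame(annotations)
  if (nrow(ann) == 0L) return(seizure_annotation(numeric(0), numeric(0)))
  if (is.unsorted(ann$onset_s)) {
    stop("annotations must be sorted by onset", call. = FALSE)
  }
  gap_s <- gap_min * 60
  lead_onset <- ann$onset_s[1]
  lead_offset <- ann$offset_s[1]
  out_on <- numeric(0); out_off <- numeric(0)
  prev_onset <- ann$onset_s[1]
  for (i in seq_len(nrow(ann))[-1]) {
    if (ann$onset_s[i] - prev_onset < gap_s) {
      lead_offset <- max(lead_offset, ann$offset_s[i]) # absorb into chain
    } else {
      out_on <- c(out_on, lead_onset); out_off <- c(out_off, lead_offset)
      lead_onset <- ann$onset_s[i]; lead_offset <- ann$offset_s[i]
    }
    prev_onset <- ann$onset_s[i]
  }
  out_on <- c(out_on, lead_onset); out_off <- c(out_off, lead_offset)
  res <- seizure_annotation(out_on, out_off)
  if ("clock_hour" %in% names(ann)) {
    res$clock_hour <- ann$clock_hour[match(res$onset_s, ann$onset_s)]
  }
  res
}

#' Label a recording timeline as preictal / interictal / excluded
#'
#' Preictal is the interval `[onset - preictal_start_min, onset -
#' preictal_end_min)` before each leading seizure (defaults: 35 to 5 min
#' before onset). Interictal is any time at least `interictal_margin_h`
#' hours away from every annotated seizure, merged or not (the conservative
#' reading). Everything else -- ictal time, the gap closer than the margin,
#' and the last minutes before onset -- is excluded. Preictal windows of
#' distinct leading seizures that would overlap are truncated (the later
#' window starts where the earlier one ends) with a warning.
#'
#' @param recording An [eeg_recording()], or a single number giving the
#'   recording duration in seconds.
#' @param leading Leading-seizure annotations (see
#'   [merge_leading_seizures()]).
#' @param preictal_start_min,preictal_end_min Preictal window bounds in
#'   minutes before onset.
#' @param interictal_margin_h Minimum distance (hours) from any seizure for
#'   interictal time.
#' @param all_annotations Full (pre-merge) annotation table used for the
#'   interictal distance rule; defaults to `leading`.
#' @return Data frame with columns `start_s`, `end_s`, `label`; intervals
#'   are half-open `[start_s, end_s)`, contiguous, and cover the recording.
#' @export
label_timeline <- function(recording, leading,
                           preictal_start_min = 35, preictal_end_min = 5,
                           interictal_margin_h = 4,
                           all_annotations = leading) {
  duration <- if (inherits(recording, "eeg_recording")) {
    recording_duration(recording)
  } else {
    stopifnot_scalar(recording, "recording", positive = TRUE)
  }
  leading <- as.data.frame(leading)
  allann <- as.data.frame(all_annotations)
  if (nrow(leading) && (min(leading$onset_s) < 0 ||
                        max(leading$offset_s) > duration)) {
    stop("leading seizures must lie within the recording span", call. = FALSE)
  }

  clip <- function(a, b) c(max(0, a), min(duration, b))

  # preictal intervals, truncated on overlap
  pre <- NULL
  if (nrow(leading)) {
    starts <- leading$onset_s - preictal_start_min * 60
    ends <- leading$onset_s - preictal_end_min * 60
    last_end <- -Inf
    for (k in seq_along(starts)) {
      iv <- clip(starts[k], ends[k])
      if (iv[1] < last_end) {
        warning("overlapping preictal windows; truncating the later one")
        iv[1] <- last_end
      }
      if (iv[2] > iv[1]) {
        pre <- rbind(pre, iv)
        last_end <- iv[2]
      }
    }
  }

  # exclusion zones: margin around every annotated seizure
  zones <- NULL
  margin_s <- interictal_margin_h * 3600
  if (nrow(allann)) {
    zones <- cbind(pmax(0, allann$onset_s - margin_s),
                   pmin(duration, allann$offset_s + margin_s))
  }

  brk <- sort(unique(c(0, duration, pre, zones)))
  brk <- brk[brk >= 0 & brk <= duration]
  mid <- (head(brk, -1) + tail(brk, -1)) / 2
  in_any <- function(m, ivs) {
    if (is.null(ivs)) return(rep(FALSE, length(m)))
    out <- rep(FALSE, length(m))
    for (k in seq_len(nrow(ivs))) out <- out | (m >= ivs[k, 1] & m < ivs[k, 2])
    out
  }
  label <- ifelse(in_any(mid, pre), "preictal",
                  ifelse(in_any(mid, zones), "excluded", "interictal"))

  out <- data.frame(start_s = head(brk, -1), end_s = tail(brk, -1),
                    label = label, stringsAsFactors = FALSE)
  # merge adjacent intervals with equal labels
  keep <- c(TRUE, label[-1] != label[-length(label)])
  grp <- factor(cumsum(keep), levels = unique(cumsum(keep)))
  data.frame(
    start_s = as.numeric(tapply(out$start_s, grp, min)),
    end_s = as.numeric(tapply(out$end_s, grp, max)),
    label = out$label[keep],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Split a recording into labelled, half-overlapping windows
#'
#' Windows of `window_s` seconds start every `window_s * (1 - overlap)`
#' seconds (30-s windows with 50% overlap by default, i.e. a 15-s hop).
#' A window keeps the label of the timeline interval that wholly contains
#' it; windows straddling two intervals are `excluded`.
#'
#' @param recording An [eeg_recording()].
#' @param labels Optional timeline from [label_timeline()]; if omitted all
#'   windows are labelled `interictal`.
#' @param window_s Window length in seconds.
#' @param overlap Fractional overlap in `[0, 1)`.
#' @return Data frame with columns `start_s`, `label`, `clock_hour`.
#' @export
segment_stream <- function(recording, labels = NULL, window_s = 30,
                           overlap = 0.5) {
  stopifnot(inherits(recording, "eeg_recording"))
  duration <- recording_duration(recording)
  if (duration < window_s) {
    warning("recording shorter than one window; returning no windows")
    return(data.frame(start_s = numeric(0), label = character(0),
                      clock_hour = numeric(0)))
  }
  hop <- window_s * (1 - overlap)
  starts <- seq(0, duration - window_s, by = hop)
  lab <- rep("interictal", length(starts))
  if (!is.null(labels)) {
    lab <- vapply(starts, function(s) {
      hit <- labels$label[labels$start_s <= s & labels$end_s >= s + window_s]
      if (length(hit) == 1L) hit else "excluded"
    }, character(1))
  }
  data.frame(
    start_s = starts,
    label = lab,
    clock_hour = ((recording$start_clock_s + starts) / 3600) %% 24,
    stringsAsFactors = FALSE
  )
}

#' Trimmed short-time Fourier transform of one 30-s window
#'
#' Each channel is framed into 1-s (256-sample) frames with 50% overlap
#' (128-sample hop), giving 59 frames. Each frame is demeaned, tapered with
#' a Hann (raised-cosine) window, and transformed; the one-sided magnitude
#' spectrum has 129 bins. The first frame and the last two are trimmed to
#' suppress edge effects (59 -> 56) and the DC bin is dropped (129 -> 128),
#' so a valid input of `n` channels yields an `n x 56 x 128` array.
#' Demeaning plus bin dropping together make the output exactly invariant
#' to constant offsets, which is what "removing the DC component" must
#' achieve for a tapered transform.
#'
#' @param window Numeric matrix `n_channels x 7680` (30 s at 256 Hz), or a
#'   vector for a single channel.
#' @param sampling_rate Sampling rate in Hz; frames are 1 s long.
#' @param log_magnitude If `TRUE`, return `log(1 + magnitude)`.
#' @return Object of class `stft_segment`: list with `values` (array
#'   `n x 56 x 128`), `label`, `start_s`, `clock_hour` (the latter three
#'   `NA` until attached by [preprocess_recording()]).
#' @export
compute_stft <- function(window, sampling_rate = 256, log_magnitude = FALSE) {
  if (is.null(dim(window))) window <- matrix(window, nrow = 1L)
  n_expected <- as.integer(30 * sampling_rate)
  if (ncol(window) != n_expected) {
    stop(sprintf("each channel must have exactly %d samples (30 s at %g Hz), got %d",
                 n_expected, sampling_rate, ncol(window)), call. = FALSE)
  }
  frame_len <- as.integer(sampling_rate)          # 256
  hop <- frame_len %/% 2L                         # 128
  n_frames <- (n_expected - frame_len) %/% hop + 1L # 59
  keep_frames <- seq(2L, n_frames - 2L)           # trim first + last two -> 56
  n_bins <- frame_len %/% 2L + 1L                 # 129 one-sided
  taper <- 0.5 - 0.5 * cos(2 * pi * (0:(frame_len - 1L)) / frame_len)

  frame_idx <- outer(seq_len(frame_len), (seq_len(n_frames) - 1L) * hop, "+")
  n_ch <- nrow(window)
  values <- array(0, dim = c(n_ch, length(keep_frames), n_bins - 1L))
  for (ch in seq_len(n_ch)) {
    fr <- matrix(window[ch, ][frame_idx], nrow = frame_len)  # 256 x 59
    fr <- sweep(fr, 2L, colMeans(fr))                        # demean (DC removal)
    sp <- Mod(mvfft(fr * taper))[seq_len(n_bins), , drop = FALSE]
    values[ch, , ] <- t(sp[-1L, keep_frames, drop = FALSE])  # drop DC bin
  }
  if (log_magnitude) values <- log1p(values)
  structure(
    list(values = values, label = NA_character_, start_s = NA_real_,
         clock_hour = NA_real_),
    class = "stft_segment"
  )
}

#' Preprocess a recording into labelled STFT segments
#'
#' Full preprocessing chain: merge leading seizures, label the timeline,
#' window the signal, and compute the trimmed STFT of every non-excluded
#' window.
#'
#' @param recording An [eeg_recording()].
#' @param annotations A [seizure_annotation()] table (may be empty).
#' @param log_magnitude Passed to [compute_stft()].
#' @param keep Labels to retain (default preictal and interictal).
#' @param ... Passed to [label_timeline()] (labelling parameters).
#' @return List with `x` (list of `n x 56 x 128` arrays), `meta` (data
#'   frame: `id`, `start_s`, `label`, `clock_hour`), `leading` (the merged
#'   annotations), and `timeline`.
#' @export
preprocess_recording <- function(recording, annotations,
                                 log_magnitude = FALSE,
                                 keep = c("preictal", "interictal"), ...) {
  leading <- merge_leading_seizures(annotations)
  timeline <- label_timeline(recording, leading,
                             all_annotations = annotations, ...)
  windows <- segment_stream(recording, timeline)
  windows <- windows[windows$label %in% keep, , drop = FALSE]
  fs <- recording$sampling_rate
  x <- lapply(windows$start_s, function(s) {
    i0 <- round(s * fs) + 1L
    seg <- recording$samples[, i0:(i0 + 30L * fs - 1L), drop = FALSE]
    compute_stft(seg, fs, log_magnitude = log_magnitude)$values
  })
  meta <- data.frame(
    id = seq_len(nrow(windows)),
    start_s = windows$start_s,
    label = windows$label,
    clock_hour = windows$clock_hour,
    stringsAsFactors = FALSE
  )
  list(x = x, meta = meta, leading = leading, timeline = timeline)
}

#' Sum cohort bookkeeping columns of a patient metadata table
#'
#' @param metadata Data frame with columns `n_leading` and `interictal_h`
#'   (e.g. [generate_metadata_table()] output or the packaged cohort
#'   table, see [epilepsiae_cohort()]).
#' @return List with `total_leading` and `total_interictal_h`.
#' @export
dataset_summary <- function(metadata) {
  if (!all(c("n_leading", "interictal_h") %in% names(metadata))) {
    stop("metadata must have columns `n_leading` and `interictal_h`",
         call. = FALSE)
  }
  list(
    total_leading = sum(metadata$n_leading),
    total_interictal_h = sum(metadata$interictal_h)
  )
}

#' Load the packaged clinical cohort summary table
#'
#' A 30-patient scalp-EEG cohort description (per-patient seizure counts,
#' leading-seizure counts after <30-min merging, and interictal hours)
#' shipped as a plain CSV for bookkeeping tests and examples.
#'
#' @return Data frame with columns `patient`, `gender`, `age`,
#'   `n_seizures`, `n_leading`, `interictal_h`.
#' @export
epilepsiae_cohort <- function() {
  path <- system.file("extdata", "epilepsiae_scalp_cohort.csv",
                      package = "seizecast", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
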