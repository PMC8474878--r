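#' Configuration for the synthetic EEG generator
#'
#' Collects and validates every knob of the synthetic-data world: recording
#' geometry, the circadian mixture that seizure onsets are drawn from, and
#' the strength of the preictal slow-wave signature. The generator emulates
#' the properties the downstream pipeline relies on -- 256 Hz multichannel
#' EEG, interictal 1/f background, preictal windows with elevated 1--4 Hz
#' band power, and onsets whose hour-of-day follows a configurable mixture
#' -- not physiologically realistic EEG.
#'
#' @param n_channels Number of EEG channels (the clinical reference setting
#'   uses 19 scalp electrodes).
#' @param sampling_rate Sampling rate in Hz. The preprocessing contract
#'   assumes 256 Hz.
#' @param duration_s Recording duration in seconds.
#' @param n_seizures Number of seizures to place in the recording.
#' @param seizure_hour_distribution Data frame with columns `hour` and
#'   `weight` describing a wrapped-Gaussian mixture over clock hours
#'   (0--24) from which onset hours are drawn. Weights must sum to 1.
#' @param hour_sd Standard deviation (hours) of each mixture component.
#' @param preictal_len_min Length in minutes of the window before each
#'   onset that carries the preictal signature.
#' @param preictal_effect Multiplicative gain applied to total 1--4 Hz band
#'   power inside preictal windows; 1 means no signature, values > 1 are
#'   detectable in proportion to their size.
#' @param noise_sd Amplitude scale of the background noise (arbitrary
#'   units; scalp EEG is typically tens of microvolts).
#' @param affected_channels Integer indices of channels carrying the
#'   preictal signature. Defaults to all channels.
#' @param min_gap_min Minimum allowed gap between consecutive onsets, in
#'   minutes.
#' @param seizure_len_s Ictal duration in seconds (onset to offset).
#' @param start_clock_s Clock time of the first sample, in seconds since
#'   midnight. Hour-of-day of a sample at time `t` is
#'   `((start_clock_s + t) / 3600) %% 24`.
#' @param n_patients Number of synthetic patients (used by
#'   [generate_metadata_table()] and [generate_dataset()]).
#' @param seed Integer seed; every generator output is bit-identical for a
#'   fixed seed.
#'
#' @return An object of class `synth_config` (a validated list).
#' @seealso [generate_seizure_schedule()], [generate_recording()],
#'   [generate_dataset()]
#' @export
synth_config <- function(n_channels = 19L,
                         sampling_rate = 256,
                         duration_s = 3600,
                         n_seizures = 1L,
                         seizure_hour_distribution = data.frame(hour = 15, weight = 1),
                         hour_sd = 1.5,
                         preictal_len_min = 30,
                         preictal_effect = 2,
                         noise_sd = 1,
                         affected_channels = NULL,
                         min_gap_min = 60,
                         seizure_len_s = 60,
                         start_clock_s = 0,
                         n_patients = 1L,
                         seed = 1L) {
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  stopifnot_scalar(duration_s, "duration_s", positive = TRUE)
  stopifnot_scalar(n_channels, "n_channels", positive = TRUE)
  stopifnot_scalar(hour_sd, "hour_sd", positive = TRUE)
  stopifnot_scalar(preictal_effect, "preictal_effect")
  if (preictal_effect < 1) stop("`preictal_effect` must be >= 1", call. = FALSE)
  if (n_seizures < 0) stop("`n_seizures` must be >= 0", call. = FALSE)
  mix <- as.data.frame(seizure_hour_distribution)
  if (!all(c("hour", "weight") %in% names(mix))) {
    stop("`seizure_hour_distribution` needs columns `hour` and `weight`",
         call. = FALSE)
  }
  if (abs(sum(mix$weight) - 1) > 1e-8) {
    stop("mixture weights must sum to 1", call. = FALSE)
  }
  if (any(mix$weight < 0)) stop("mixture weights must be >= 0", call. = FALSE)
  if (is.null(affected_channels)) affected_channels <- seq_len(n_channels)
  if (any(affected_channels < 1 | affected_channels > n_channels)) {
    stop("`affected_channels` out of range", call. = FALSE)
  }
  structure(
    list(
      n_channels = as.integer(n_channels),
      sampling_rate = sampling_rate,
      duration_s = duration_s,
      n_seizures = as.integer(n_seizures),
      seizure_hour_distribution = mix,
      hour_sd = hour_sd,
      preictal_len_min = preictal_len_min,
      preictal_effect = preictal_effect,
      noise_sd = noise_sd,
      affected_channels = as.integer(affected_channels),
      min_gap_min = min_gap_min,
      seizure_len_s = seizure_len_s,
      start_clock_s = start_clock_s,
      n_patients = as.integer(n_patients),
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Draw seizure-onset clock hours from the configured circadian mixture
#'
#' Samples hour-of-day values from the wrapped-Gaussian mixture in
#' `config$seizure_hour_distribution`. This is the primitive behind
#' [generate_seizure_schedule()]; exposing it makes the distributional
#' contract directly testable.
#'
#' @param config A [synth_config()].
#' @param n Number of draws.
#' @param seed Optional seed overriding `config$seed`.
#' @return Numeric vector of hours in `[0, 24)`.
#' @export
sample_seizure_hours <- function(config, n, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  if (n == 0) return(numeric(0))
  mix <- config$seizure_hour_distribution
  with_seed(seed, {
    comp <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$weight)
    (rnorm(n, mean = mix$hour[comp], sd = config$hour_sd)) %% 24
  })
}

#' Generate a seizure schedule realising the configured hour-of-day mixture
#'
#' Places `config$n_seizures` onsets inside the recording span so that the
#' hour-of-day of each onset is a draw from the configured mixture and
#' consecutive onsets are at least `min_gap_min` minutes apart. Placement
#' is rejection-based: candidate onsets are proposed at the sampled clock
#' hour on a uniformly chosen day, and candidates violating the span or the
#' gap are re-drawn.
#'
#' @inheritParams sample_seizure_hours
#' @return A data frame of class `seizure_annotation` with columns
#'   `onset_s`, `offset_s`, `clock_hour`, sorted by onset.
#' @export
generate_seizure_schedule <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_seizures
  if (n == 0L) {
    return(seizure_annotation(numeric(0), numeric(0)))
  }
  span <- config$duration_s - config$seizure_len_s
  gap_s <- config$min_gap_min * 60
  if (span <= 0 || (n - 1) * gap_s + config$seizure_len_s > config$duration_s) {
    stop(sprintf(
      "duration %.0f s is too short to place %d seizures %0.f min apart",
      config$duration_s, n, config$min_gap_min
    ), call. = FALSE)
  }
  n_days <- max(1L, ceiling(config$duration_s / 86400))
  with_seed(seed, {
    onsets <- numeric(0)
    attempts <- 0L
    max_attempts <- 1000L * n
    while (length(onsets) < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      hour <- sample_seizure_hours(config, 1L, seed = NULL)
      day <- sample.int(n_days, 1L) - 1L
      t <- day * 86400 + hour * 3600 - config$start_clock_s
      if (t < 0 || t > span) next
      if (length(onsets) && any(abs(onsets - t) < gap_s)) next
      onsets <- c(onsets, t)
    }
    if (length(onsets) < n) {
      stop(sprintf(
        "could not place %d seizures with the requested gap inside %.0f s",
        n, config$duration_s
      ), call. = FALSE)
    }
    onsets <- sort(onsets)
    ann <- seizure_annotation(onsets, onsets + config$seizure_len_s)
    ann$clock_hour <- ((config$start_clock_s + ann$onset_s) / 3600) %% 24
    ann
  })
}

# Band-limit a signal by zeroing FFT coefficients outside [lo, hi] Hz.
# Uses nextn() padding so arbitrary durations do not hit slow FFT sizes.
band_component <- function(x, fs, lo, hi) {
  n <- length(x)
  np <- stats::nextn(n, factors = c(2, 3, 5))
  xp <- c(x, numeric(np - n))
  X <- fft(xp)
  freq <- (seq_len(np) - 1) / np * fs
  freq <- pmin(freq, fs - freq) # two-sided
  X[freq < lo | freq > hi] <- 0
  Re(fft(X, inverse = TRUE) / np)[seq_len(n)]
}

# 1/f-shaped ("pink-ish") noise via FFT amplitude shaping of white noise.
pink_noise <- function(n, fs) {
  np <- stats::nextn(n, factors = c(2, 3, 5))
  X <- fft(rnorm(np))
  freq <- (seq_len(np) - 1) / np * fs
  freq <- pmin(freq, fs - freq)
  scale <- 1 / sqrt(pmax(freq, 0.5)) # flatten below 0.5 Hz, kill DC drift
  scale[1] <- 0
  x <- Re(fft(X * scale, inverse = TRUE) / np)[seq_len(n)]
  x / sd(x)
}

#' Generate a multichannel synthetic EEG recording
#'
#' Background activity on every channel is independent 1/f-shaped noise
#' plus a white-noise floor, which keeps all STFT bins non-degenerate. A
#' separate 1--4 Hz band-limited component is superimposed; inside
#' `[onset - preictal_len_min, onset)` of every scheduled seizure its gain
#' on the affected channels is raised so that the total 1--4 Hz band power
#' of the channel equals `preictal_effect` times its interictal value (the
#' gain is solved from the measured band powers of the two components, so
#' the contract holds for any `preictal_effect >= 1`).
#'
#' @param config A [synth_config()].
#' @param schedule A seizure annotation table, typically from
#'   [generate_seizure_schedule()].
#' @param seed Optional seed overriding `config$seed`.
#' @return An [eeg_recording()].
#' @export
generate_recording <- function(config, schedule = NULL, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(schedule)) schedule <- generate_seizure_schedule(config, seed = seed)
  if (nrow(schedule) && max(schedule$offset_s) > config$duration_s) {
    stop("schedule extends beyond the recording duration", call. = FALSE)
  }
  fs <- config$sampling_rate
  n_samp <- round(config$duration_s * fs)
  tgrid <- (seq_len(n_samp) - 1) / fs

  # preictal gain profile over time, shared across affected channels
  gain_mask <- rep(FALSE, n_samp)
  if (nrow(schedule)) {
    for (k in seq_len(nrow(schedule))) {
      a <- schedule$onset_s[k] - config$preictal_len_min * 60
      b <- schedule$onset_s[k]
      gain_mask <- gain_mask | (tgrid >= a & tgrid < b)
    }
  }

  with_seed(seed, {
    samples <- matrix(0, nrow = config$n_channels, ncol = n_samp)
    for (ch in seq_len(config$n_channels)) {
      bg <- config$noise_sd * (0.8 * pink_noise(n_samp, fs) + 0.4 * rnorm(n_samp))
      slow <- band_component(rnorm(n_samp), fs, 1, 4)
      slow <- 0.6 * config$noise_sd * slow / sd(slow)
      x <- bg + slow
      if (config$preictal_effect > 1 && ch %in% config$affected_channels &&
          any(gain_mask)) {
        p_bg <- mean(band_component(bg, fs, 1, 4)^2)
        p_slow <- mean(slow^2)
        g <- sqrt((config$preictal_effect * (p_bg + p_slow) - p_bg) / p_slow)
        x[gain_mask] <- bg[gain_mask] + g * slow[gain_mask]
      }
      samples[ch, ] <- x
    }
    eeg_recording(
      samples = samples,
      sampling_rate = fs,
      channel_labels = sprintf("SYN%02d", seq_len(config$n_channels)),
      start_clock_s = config$start_clock_s
    )
  })
}

#' Generate a per-patient metadata table
#'
#' Simulates one seizure schedule per synthetic patient and summarises it
#' the way clinical dataset descriptions tabulate cohorts: seizure count,
#' leading-seizure count after merging clustered seizures
#' ([merge_leading_seizures()]), and interictal hours under the standard
#' labelling rules ([label_timeline()]).
#'
#' @param config A [synth_config()]; `config$n_patients` rows are produced.
#' @return Data frame with columns `patient`, `n_seizures`, `n_leading`,
#'   `interictal_h`.
#' @export
generate_metadata_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  rows <- lapply(seq_len(config$n_patients), function(p) {
    sched <- generate_seizure_schedule(config, seed = config$seed + p - 1L)
    leading <- merge_leading_seizures(sched)
    tl <- label_timeline(config$duration_s, leading, all_annotations = sched)
    inter <- tl[tl$label == "interictal", , drop = FALSE]
    data.frame(
      patient = sprintf("SynPat%d", p),
      n_seizures = nrow(sched),
      n_leading = nrow(leading),
      interictal_h = sum(inter$end_s - inter$start_s) / 3600
    )
  })
  do.call(rbind, rows)
}

#' Generate a complete synthetic dataset
#'
#' One recording + annotation table per synthetic patient, plus the
#' cohort metadata table. Patient `p` uses seed `config$seed + p - 1`.
#'
#' @param config A [synth_config()].
#' @return List with elements `recordings`, `annotations` (parallel lists)
#'   and `metadata`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  schedules <- lapply(seq_len(config$n_patients), function(p) {
    generate_seizure_schedule(config, seed = config$seed + p - 1L)
  })
  recordings <- lapply(seq_len(config$n_patients), function(p) {
    generate_recording(config, schedules[[p]], seed = config$seed + p - 1L)
  })
  metadata <- generate_metadata_table(config)
  structure(
    list(recordings = recordings, annotations = schedules, metadata = metadata),
    class = "generated_dataset"
  )
}
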