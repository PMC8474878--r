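test_that("merge rule: direct examples, chaining, and the strict 30-min boundary", {
  m <- function(on) seizure_annotation(on, on + 60)
  # onsets at 0, 20 min, 100 min -> leading onsets {0, 100 min}
  out <- merge_leading_seizures(m(c(0, 1200, 6000)))
  expect_equal(out$onset_s, c(0, 6000))
  # 22 seizures each 25 min apart chain into a single leading seizure
  out <- merge_leading_seizures(m(seq(0, by = 25 * 60, length.out = 22)))
  expect_equal(nrow(out), 1L)
  expect_equal(out$onset_s, 0)
  # exactly 30 min apart is NOT merged ("<30 min" is strict)
  out <- merge_leading_seizures(m(c(0, 1800)))
  expect_equal(nrow(out), 2L)
  # unsorted input errors
  expect_error(merge_leading_seizures(data.frame(onset_s = c(10, 0),
                                                 offset_s = c(20, 5))),
               "sorted")
})

test_that("merge_leading_seizures is idempotent", {
  set.seed(31)
  for (rep in 1:20) {
    on <- sort(runif(15, 0, 6 * 3600))
    ann <- seizure_annotation(on, on + 30)
    once <- merge_leading_seizures(ann)
    twice <- merge_leading_seizures(once)
    expect_equal(twice$onset_s, once$onset_s)
    expect_equal(twice$offset_s, once$offset_s)
  }
})

test_that("label_timeline applies the preictal and interictal distance rules", {
  onset <- 6 * 3600
  leading <- seizure_annotation(onset, onset + 60)
  tl <- label_timeline(10 * 3600, leading)
  label_at <- function(t) tl$label[tl$start_s <= t & tl$end_s > t]
  expect_equal(label_at(onset - 20 * 60), "preictal")
  expect_equal(label_at(onset - 2 * 3600), "excluded")
  expect_equal(label_at(onset - 5 * 3600), "interictal")
  # preictal bounds are [onset - 35 min, onset - 5 min)
  pre <- tl[tl$label == "preictal", ]
  expect_equal(pre$start_s, onset - 35 * 60)
  expect_equal(pre$end_s, onset - 5 * 60)
})

test_that("label_timeline edge cases: no seizures, clipped preictal, overlap warning", {
  tl <- label_timeline(3600, seizure_annotation(numeric(0), numeric(0)))
  expect_equal(tl$label, "interictal")
  expect_equal(tl$end_s - tl$start_s, 3600)
  # onset 30 min in: preictal clipped to the recording span
  tl <- label_timeline(5 * 3600, seizure_annotation(1800, 1860))
  pre <- tl[tl$label == "preictal", ]
  expect_equal(pre$start_s, 0)
  expect_equal(pre$end_s, 1800 - 300)
  # two seizures 20 min apart (as passed, unmerged) have overlapping
  # preictal windows -> warning + truncation
  lead <- seizure_annotation(c(7200, 7200 + 20 * 60), c(7230, 7230 + 20 * 60))
  expect_warning(tl <- label_timeline(6 * 3600, lead), "truncat")
  pre <- tl[tl$label == "preictal", ]
  expect_true(all(diff(as.vector(t(pre[, c("start_s", "end_s")]))) >= 0))
})

test_that("preictal and interictal never overlap (property)", {
  set.seed(17)
  for (rep in 1:10) {
    on <- sort(runif(4, 3600, 10 * 3600))
    ann <- seizure_annotation(on, on + 45)
    tl <- suppressWarnings(
      label_timeline(12 * 3600, merge_leading_seizures(ann),
                     all_annotations = ann)
    )
    # intervals are contiguous and partition the recording
    expect_equal(tl$start_s[-1], tl$end_s[-nrow(tl)])
    expect_equal(tl$start_s[1], 0)
    expect_equal(tl$end_s[nrow(tl)], 12 * 3600)
    # interictal intervals keep the 4 h margin from every seizure
    inter <- tl[tl$label == "interictal", ]
    if (nrow(inter)) {
      for (k in seq_len(nrow(inter))) {
        dist <- pmax(on - inter$end_s[k], inter$start_s[k] - (on + 45))
        expect_true(all(dist >= 4 * 3600 - 1e-9))
      }
    }
  }
})

test_that("segment_stream window arithmetic matches the count formula", {
  mk_rec <- function(duration_s, fs = 2) {
    eeg_recording(matrix(0, 1, duration_s * fs), fs)
  }
  expect_equal(nrow(segment_stream(mk_rec(60))), 3L)   # starts 0, 15, 30
  expect_equal(nrow(segment_stream(mk_rec(30))), 1L)
  # 13 h of recording: floor((13*3600 - 30)/15) + 1 windows
  expect_equal(nrow(segment_stream(mk_rec(13 * 3600))), 3119L)
  expect_warning(out <- segment_stream(mk_rec(20)), "shorter")
  expect_equal(nrow(out), 0L)
})

test_that("segment_stream labels whole windows and excludes straddlers", {
  rec <- eeg_recording(matrix(0, 1, 240 * 4), 4, start_clock_s = 13.5 * 3600)
  labels <- data.frame(start_s = c(0, 120), end_s = c(120, 240),
                       label = c("interictal", "preictal"))
  w <- segment_stream(rec, labels)
  expect_equal(w$label[w$start_s == 0], "interictal")
  expect_equal(w$label[w$start_s == 105], "excluded") # straddles 120 s
  expect_equal(w$label[w$start_s == 120], "preictal")
  expect_equal(w$clock_hour[1], 13.5)
})

test_that("compute_stft produces the trimmed 56 x 128 grid", {
  x <- matrix(rnorm(19 * 7680), nrow = 19)
  s <- compute_stft(x)
  expect_equal(dim(s$values), c(19, 56, 128))
  expect_true(all(is.finite(s$values)))
  expect_error(compute_stft(matrix(0, 1, 7000)), "7680")
})

test_that("compute_stft rejects DC and is offset-invariant", {
  s0 <- compute_stft(matrix(5, 1, 7680))
  expect_lt(max(abs(s0$values)), 1e-6)
  set.seed(4)
  x <- matrix(rnorm(7680), 1)
  expect_lt(max(abs(compute_stft(x)$values - compute_stft(x + 100)$values)),
            1e-9)
})

test_that("a 10 Hz sinusoid peaks at the 10 Hz bin in every retained frame", {
  t <- (0:7679) / 256
  s <- compute_stft(matrix(sin(2 * pi * 10 * t), 1))
  peaks <- apply(s$values[1, , ], 1L, which.max)
  expect_true(all(peaks == 10L)) # bin k is k Hz after dropping DC
  # frame-wise DFT oracle for the peak magnitude
  taper <- 0.5 - 0.5 * cos(2 * pi * (0:255) / 256)
  fr <- sin(2 * pi * 10 * t[129:384]) # frame index 2 (first retained)
  oracle <- Mod(fft((fr - mean(fr)) * taper))[11]
  expect_equal(s$values[1, 1, 10], oracle, tolerance = 1e-10)
})

test_that("retained spectral energy scales quadratically with amplitude", {
  set.seed(8)
  x <- matrix(rnorm(7680), 1)
  e1 <- sum(compute_stft(x)$values^2)
  e3 <- sum(compute_stft(3 * x)$values^2)
  expect_equal(e3 / e1, 9, tolerance = 1e-10)
})

test_that("dataset_summary reproduces cohort totals from the packaged table", {
  tab <- epilepsiae_cohort()
  s <- dataset_summary(tab)
  expect_equal(s$total_leading, 261)
  expect_equal(s$total_interictal_h, 2881.4)
  # single-row and empty tables
  s1 <- dataset_summary(tab[1, ])
  expect_equal(s1$total_leading, 11)
  expect_equal(s1$total_interictal_h, 68.9)
  s0 <- dataset_summary(tab[0, ])
  expect_equal(s0$total_leading, 0)
  expect_equal(s0$total_interictal_h, 0)
  expect_error(dataset_summary(data.frame(a = 1)), "columns")
})

test_that("recordings round-trip through the array archive", {
  rec <- eeg_recording(matrix(round(rnorm(2 * 100), 6), 2), 50,
                       channel_labels = c("A", "B"), start_clock_s = 3600)
  path <- file.path(tempdir(), "rec-archive")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$samples, rec$samples, ignore_attr = TRUE)
  expect_equal(back$sampling_rate, 50)
  expect_equal(back$channel_labels, c("A", "B"))
  expect_equal(back$start_clock_s, 3600)
  expect_error(read_recording(file.path(tempdir(), "no-such-dir")),
               "archive")
  expect_error(read_recording(path, format = "EDF"), "EDF")
})

test_that("annotations round-trip through CSV", {
  ann <- generate_seizure_schedule(
    synth_config(duration_s = 86400, n_seizures = 3L, min_gap_min = 90,
                 seed = 13L)
  )
  path <- tempfile(fileext = ".csv")
  write_annotations(ann, path)
  back <- read_annotations(path)
  expect_equal(back$onset_s, ann$onset_s)
  expect_equal(back$clock_hour, ann$clock_hour)
})
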