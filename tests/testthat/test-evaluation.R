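test_that("segment_auc: separation, null, the worked four-point case, errors", {
  expect_equal(segment_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(segment_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  set.seed(19)
  expect_lt(abs(segment_auc(runif(4000), rbinom(4000, 1, 0.5)) - 0.5), 0.05)
  expect_error(segment_auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("segment_auc agrees exactly with the pairwise oracle up to n = 200", {
  set.seed(23)
  for (n in c(10, 50, 200)) {
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(runif(n), 2) # rounding forces ties
    expect_equal(segment_auc(scores, labels), auc_oracle(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("risk_timeline identity limit and constant input", {
  tl <- risk_timeline(1:10, rep(0.8, 10), rep(0, 10))
  expect_equal(tl$smoothed, rep(0.8, 10))
  # gate = +Inf, window = 1 returns raw scores unchanged
  set.seed(3)
  sc <- runif(20)
  un <- runif(20, 0, 5)
  tl <- risk_timeline(1:20, sc, un, smooth_window = 1L,
                      uncertainty_gate = Inf)
  expect_equal(tl$smoothed, sc)
})

test_that("risk_timeline gates on uncertainty and ramps after a step", {
  # all points above the gate -> nothing retained
  tl <- risk_timeline(1:5, runif(5), rep(2, 5))
  expect_true(all(!tl$retained))
  expect_true(all(is.na(tl$smoothed)))

  # step 0 -> 1 at index 101: the 50-step backward mean reaches 1 exactly
  # 50 retained points after the step
  n <- 200
  sc <- c(rep(0, 100), rep(1, 100))
  tl <- risk_timeline(seq_len(n), sc, rep(0, n))
  ramp <- tl$smoothed[101:150]
  expect_equal(ramp, (1:50) / 50)
  expect_equal(tl$smoothed[150], 1)
  expect_true(all(tl$smoothed[151:200] == 1))
  # gated-out points carry NA, not zero, and do not enter the average
  un <- rep(0, n); un[120:130] <- 5
  tl2 <- risk_timeline(seq_len(n), sc, un)
  expect_true(all(is.na(tl2$smoothed[120:130])))
  # 19 retained post-step points before the gap, so the 50th is index 161
  expect_lt(tl2$smoothed[160], 1)
  expect_equal(tl2$smoothed[161], 1)
})

test_that("risk_timeline validates alignment and ordering", {
  expect_error(risk_timeline(c(1, 1, 2), 1:3, 1:3), "increasing")
  expect_error(risk_timeline(1:3, 1:2, 1:3), "aligned")
  expect_equal(nrow(risk_timeline(numeric(0), numeric(0), numeric(0))), 0L)
})

test_that("period_split produces leakage-free folds", {
  # 3 seizures -> 3 folds, each excluding its own preictal block
  onsets <- c(3600, 7200, 10800)
  meta <- data.frame(
    id = 1:60,
    start_s = seq(0, by = 200, length.out = 60)
  )
  meta$period <- assign_periods(meta$start_s, onsets)
  # preictal blocks in the 1000 s before each onset; period 4 is all interictal
  near_onset <- meta$period <= 3 &
    (onsets[pmin(meta$period, 3)] - meta$start_s) <= 1000 &
    (onsets[pmin(meta$period, 3)] - meta$start_s) > 0
  meta$label <- ifelse(near_onset, "preictal", "interictal")
  folds <- period_split(meta)
  expect_length(folds, 3L)
  all_test <- unlist(lapply(folds, `[[`, "test_ids"))
  expect_equal(sort(all_test), sort(meta$id[meta$period %in% 1:3]))
  for (f in folds) {
    expect_length(intersect(f$train_ids, f$test_ids), 0L)
    # no training segment comes from the fold's own period
    expect_true(all(meta$period[match(f$train_ids, meta$id)] != f$period))
  }
})

test_that("per-fold AUCs are computable and averageable over a 5-seizure schedule", {
  cfg <- synth_config(duration_s = 10 * 86400, n_seizures = 5L,
                      min_gap_min = 300, hour_sd = 3, seed = 77L)
  sched <- generate_seizure_schedule(cfg)
  leading <- merge_leading_seizures(sched)
  tl <- label_timeline(cfg$duration_s, leading, all_annotations = sched)
  # windows on a light grid (window arithmetic, not signal, matters here)
  starts <- seq(0, cfg$duration_s - 30, by = 900)
  lab <- vapply(starts, function(s) {
    hit <- tl$label[tl$start_s <= s & tl$end_s >= s + 30]
    if (length(hit) == 1L) hit else "excluded"
  }, character(1))
  meta <- data.frame(id = seq_along(starts), start_s = starts, label = lab)
  meta <- meta[meta$label %in% c("preictal", "interictal"), ]
  meta$period <- assign_periods(meta$start_s, leading$onset_s)
  folds <- period_split(meta)
  expect_gte(length(folds), 2L)
  # synthetic scores: preictal windows score higher on average
  set.seed(5)
  sc <- ifelse(meta$label == "preictal", rnorm(nrow(meta), 0.7, 0.15),
               rnorm(nrow(meta), 0.4, 0.15))
  aucs <- vapply(folds, function(f) {
    sel <- match(f$test_ids, meta$id)
    if (length(unique(meta$label[sel])) < 2L) return(NA_real_)
    segment_auc(sc[sel], as.integer(meta$label[sel] == "preictal"))
  }, numeric(1))
  aucs <- aucs[!is.na(aucs)]
  expect_gte(length(aucs), 1L)
  expect_gt(mean(aucs), 0.7)
})

test_that("period_split refuses a single period", {
  meta <- data.frame(id = 1:10, label = rep(c("preictal", "interictal"), 5),
                     period = 1L)
  expect_error(period_split(meta), "at least 2")
  expect_error(period_split(data.frame(id = 1)), "columns")
})

test_that("assign_periods places preictal blocks with the seizure they precede", {
  onsets <- c(1000, 5000)
  expect_equal(assign_periods(c(0, 999, 1000, 4999, 5000, 9000), onsets),
               c(1L, 1L, 2L, 2L, 3L, 3L))
})
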