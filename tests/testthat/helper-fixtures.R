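# Shared fixtures, built in code at test time.

# A tiny spec that keeps every network test fast. Input geometry is the
# standard 56 x 128 grid; only the widths shrink.
tiny_spec <- function(n_channels = 1L) {
  network_spec(n_channels, conv_filters = c(2L, 3L, 3L), dense_units = 4L)
}

random_segment <- function(n_channels = 1L, seed = 1L) {
  set.seed(seed)
  array(rnorm(n_channels * 56 * 128), dim = c(n_channels, 56, 128))
}

# Brute-force valid-padding strided 2-d convolution over a multi-channel
# input, the oracle for the im2col implementation.
conv_oracle <- function(x, W, b, kh, kw, st, sw) {
  C <- dim(x)[1]; Tn <- dim(x)[2]; Fn <- dim(x)[3]
  C_out <- nrow(W)
  T_out <- (Tn - kh) %/% st + 1L
  F_out <- (Fn - kw) %/% sw + 1L
  out <- array(0, dim = c(C_out, T_out, F_out))
  for (o in seq_len(C_out)) {
    K <- array(W[o, ], dim = c(C, kh, kw)) # rows are (c, dt, df), c fastest
    for (ti in seq_len(T_out)) {
      for (fi in seq_len(F_out)) {
        t0 <- (ti - 1L) * st
        f0 <- (fi - 1L) * sw
        out[o, ti, fi] <- sum(K * x[, t0 + seq_len(kh), f0 + seq_len(kw),
                                    drop = FALSE]) + b[o]
      }
    }
  }
  out
}

# Pairwise O(n^2) AUC oracle with half-credit for ties.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Desk-scale synthetic world used by the end-to-end recovery experiments:
# a 2-channel, 7.2-h recording with three seizures whose hours cluster at
# one clock hour, plus a 2-h seizure-free recording contributing
# interictal background at other clock hours.
gen_e2e_dataset <- function(effect, seed = 11L, start_clock_h = 0) {
  cfg <- synth_config(
    n_channels = 2L, duration_s = 7.2 * 3600, n_seizures = 3L,
    seizure_hour_distribution = data.frame(hour = start_clock_h + 5.8,
                                           weight = 1),
    hour_sd = 0.55, preictal_effect = effect, preictal_len_min = 35,
    min_gap_min = 45, start_clock_s = start_clock_h * 3600, seed = seed
  )
  sched <- generate_seizure_schedule(cfg)
  rec <- generate_recording(cfg, sched)
  pp <- preprocess_recording(rec, sched)
  cfg2 <- synth_config(n_channels = 2L, duration_s = 2 * 3600,
                       n_seizures = 0L, preictal_effect = effect,
                       seed = seed + 100L)
  rec2 <- generate_recording(cfg2)
  pp2 <- preprocess_recording(rec2, seizure_annotation(numeric(0), numeric(0)))
  list(
    x = c(pp$x, pp2$x),
    y = as.integer(c(pp$meta$label, pp2$meta$label) == "preictal"),
    hours = c(pp$meta$clock_hour, pp2$meta$clock_hour),
    start_s = c(pp$meta$start_s, pp2$meta$start_s + 1e6), # distinct blocks
    sched = sched
  )
}

# Temporal split: within each class, the earlier half of the windows
# trains and the later half tests. Avoids the optimistic leakage a random
# split would get from 50%-overlapping neighbours.
temporal_split <- function(d) {
  tr <- logical(length(d$y))
  for (cl in unique(d$y)) {
    ii <- which(d$y == cl)
    ii <- ii[order(d$start_s[ii])]
    tr[ii[seq_len(floor(length(ii) / 2))]] <- TRUE
  }
  list(train = which(tr), test = which(!tr))
}
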