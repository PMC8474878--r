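# Low-level convolution / pooling primitives.
#
# Feature maps are stored as flat numeric vectors in (channel, time, freq)
# order: flat index of (c, t, f) is c + C*(t-1) + C*T*(f-1). Convolutions
# use precomputed im2col index matrices so the forward pass is a single
# matrix multiply and the backward pass a matrix multiply plus a grouped
# scatter-add. All of this is internal; the user-facing network API lives
# in network.R.

# Index matrix for im2col: rows enumerate (c, dt, df) with channel fastest,
# columns enumerate output positions (t_out fastest, then f_out).
im2col_index <- function(C, Tn, Fn, kh, kw, st, sw) {
  T_out <- (Tn - kh) %/% st + 1L
  F_out <- (Fn - kw) %/% sw + 1L
  if (T_out < 1L || F_out < 1L) {
    stop(sprintf("kernel %dx%d does not fit input %dx%d", kh, kw, Tn, Fn),
         call. = FALSE)
  }
  c_i <- rep(seq_len(C), times = kh * kw)
  dt <- rep(rep(0:(kh - 1L), each = C), times = kw)
  df <- rep(0:(kw - 1L), each = C * kh)
  base <- c_i + C * dt + C * Tn * df
  to <- rep(seq(0L, by = st, length.out = T_out), times = F_out)
  fo <- rep(seq(0L, by = sw, length.out = F_out), each = T_out)
  list(idx = outer(base, C * to + C * Tn * fo, "+"),
       C = C, Tn = Tn, Fn = Fn, kh = kh, kw = kw,
       T_out = T_out, F_out = F_out,
       patch = C * kh * kw, n_pos = T_out * F_out,
       n_in = C * Tn * Fn)
}

# Index matrix for non-overlapping max pooling over (pt, pf) blocks,
# applied independently per channel. Columns enumerate output positions
# (channel fastest, then t_out, then f_out) so the flattened output is
# again in (channel, time, freq) order.
pool_index <- function(C, Tn, Fn, pt, pf) {
  T_out <- Tn %/% pt
  F_out <- Fn %/% pf
  ddt <- rep(0:(pt - 1L), times = pf)
  ddf <- rep(0:(pf - 1L), each = pt)
  rowoff <- C * ddt + C * Tn * ddf
  ci <- rep(seq_len(C), times = T_out * F_out)
  to <- rep(rep(0:(T_out - 1L), each = C), times = F_out)
  fo <- rep(0:(F_out - 1L), each = C * T_out)
  coloff <- ci + C * pt * to + C * Tn * pf * fo
  list(idx = outer(rowoff, coloff, "+"),
       T_out = T_out, F_out = F_out, n_out = C * T_out * F_out,
       n_in = C * Tn * Fn)
}

conv_forward <- function(x, W, b, g) {
  Xcol <- matrix(x[g$idx], nrow = g$patch)
  list(y = W %*% Xcol + b, xcol = Xcol) # y: C_out x n_pos
}

conv_backward <- function(dY, W, Xcol, g) {
  dXcol <- crossprod(W, dY)
  acc <- rowsum(as.vector(dXcol), group = as.vector(g$idx))
  dx <- numeric(g$n_in)
  dx[as.integer(rownames(acc))] <- acc[, 1L]
  list(dW = dY %*% t(Xcol), db = rowSums(dY), dx = dx)
}

pool_forward <- function(x, p) {
  M <- matrix(x[p$idx], nrow = nrow(p$idx))
  a <- max.col(t(M), ties.method = "first")
  cols <- seq_len(ncol(M))
  list(y = M[cbind(a, cols)], sel = p$idx[cbind(a, cols)])
}

pool_backward <- function(dY, sel, n_in) {
  dx <- numeric(n_in)
  dx[sel] <- dY # pooling blocks are disjoint, so no accumulation needed
  dx
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplus_inv <- function(s) ifelse(s > 30, s, log(expm1(s)))

softmax2 <- function(logits) {
  m <- max(logits)
  e <- exp(logits - m)
  e / sum(e)
}
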