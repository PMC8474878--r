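#' Architecture specification for the variational convolutional network
#'
#' The reference architecture takes an `n x 56 x 128` time--frequency
#' segment and applies: a convolution with `conv_filters[1]` kernels of
#' size `(n x 5 x 5)`, stride `(1 x 2 x 2)`, valid padding (the kernel
#' spans all EEG channels, so the channel axis collapses and subsequent
#' layers operate on a 2-D grid of feature maps); max pooling `(2 x 2)`;
#' two conv--pool blocks with `3 x 3` kernels, stride 1, valid padding and
#' `2 x 2` pooling (`conv_filters[2]` and `conv_filters[3]` kernels); a
#' fully-connected layer of `dense_units` outputs; and a final
#' fully-connected layer with 2 outputs (interictal, preictal). Defaults
#' give the reference widths 16 / 64 / 128 / 256; narrower widths are
#' supported for desk-scale experiments.
#'
#' All index bookkeeping for the convolutions and pools is precomputed
#' here, so a spec is tied to a fixed input geometry.
#'
#' @param n_channels Number of EEG channels `n`.
#' @param conv_filters Integer vector of 3 convolutional widths.
#' @param dense_units Width of the penultimate fully-connected layer.
#' @param input_time,input_freq Input grid size (56 x 128 for the standard
#'   preprocessing).
#' @param activation_slope Negative-side slope of the leaky rectifier used
#'   after every convolution and the first dense layer; 0 gives the plain
#'   rectifier. A small positive slope avoids dead-unit starts in narrow
#'   desk-scale networks.
#' @return Object of class `network_spec`.
#' @export
network_spec <- function(n_channels, conv_filters = c(16L, 64L, 128L),
                         dense_units = 256L,
                         input_time = 56L, input_freq = 128L,
                         activation_slope = 0.1) {
  stopifnot(length(conv_filters) == 3L, all(conv_filters >= 1L),
            dense_units >= 1L, n_channels >= 1L)
  f <- as.integer(conv_filters)
  g1 <- im2col_index(as.integer(n_channels), input_time, input_freq,
                     5L, 5L, 2L, 2L)
  p1 <- pool_index(f[1], g1$T_out, g1$F_out, 2L, 2L)
  g2 <- im2col_index(f[1], p1$T_out, p1$F_out, 3L, 3L, 1L, 1L)
  p2 <- pool_index(f[2], g2$T_out, g2$F_out, 2L, 2L)
  g3 <- im2col_index(f[2], p2$T_out, p2$F_out, 3L, 3L, 1L, 1L)
  p3 <- pool_index(f[3], g3$T_out, g3$F_out, 2L, 2L)
  structure(
    list(
      n_channels = as.integer(n_channels),
      conv_filters = f, dense_units = as.integer(dense_units),
      input_time = as.integer(input_time),
      input_freq = as.integer(input_freq),
      geom = list(g1 = g1, p1 = p1, g2 = g2, p2 = p2, g3 = g3, p3 = p3),
      flat = f[3] * p3$T_out * p3$F_out,
      n_classes = 2L,
      activation_slope = activation_slope
    ),
    class = "network_spec"
  )
}

#' @export
print.network_spec <- function(x, ...) {
  g <- x$geom
  cat(sprintf(
    paste0("<network_spec> input %d x %d x %d\n",
           "  conv1 %d @ (%d x 5 x 5) s(2,2) -> %d x %d x %d; pool -> %d x %d\n",
           "  conv2 %d @ 3x3 -> %d x %d; pool -> %d x %d\n",
           "  conv3 %d @ 3x3 -> %d x %d; pool -> %d x %d\n",
           "  dense %d -> dense 2\n"),
    x$n_channels, x$input_time, x$input_freq,
    x$conv_filters[1], x$n_channels, x$conv_filters[1], g$g1$T_out, g$g1$F_out,
    g$p1$T_out, g$p1$F_out,
    x$conv_filters[2], g$g2$T_out, g$g2$F_out, g$p2$T_out, g$p2$F_out,
    x$conv_filters[3], g$g3$T_out, g$g3$F_out, g$p3$T_out, g$p3$F_out,
    x$dense_units
  ))
  invisible(x)
}

# Weight-matrix shapes per layer, in the im2col layout used throughout:
# conv weights are (C_out x patch), dense weights (out x in).
layer_shapes <- function(spec) {
  f <- spec$conv_filters
  g <- spec$geom
  list(
    conv1 = list(kind = "conv", out = f[1], inn = g$g1$patch),
    conv2 = list(kind = "conv", out = f[2], inn = g$g2$patch),
    conv3 = list(kind = "conv", out = f[3], inn = g$g3$patch),
    dense1 = list(kind = "dense", out = spec$dense_units, inn = spec$flat),
    dense2 = list(kind = "dense", out = spec$n_classes, inn = spec$dense_units)
  )
}

#' Initialise Gaussian mean-field posteriors for every layer
#'
#' Each weight and bias carries an independent Gaussian posterior
#' `N(mu, sigma^2)` with `sigma = softplus(rho)` guaranteed positive.
#' Means are drawn with He-style fan-in scaling; `rho` is initialised so
#' that `sigma = sigma_init` everywhere (a weakly stochastic start).
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed.
#' @param sigma_init Initial posterior standard deviation.
#' @param bias_init Initial bias mean (zero by default).
#' @return List of `variational_layer` objects with elements `mu_w`,
#'   `rho_w`, `mu_b`, `rho_b`, `kind`.
#' @export
init_variational_layers <- function(spec, seed = 1L, sigma_init = 0.02,
                                    bias_init = 0) {
  shapes <- layer_shapes(spec)
  rho0 <- softplus_inv(sigma_init)
  with_seed(seed, lapply(shapes, function(s) {
    structure(
      list(
        kind = s$kind,
        mu_w = matrix(rnorm(s$out * s$inn, sd = sqrt(2 / s$inn)),
                      nrow = s$out, ncol = s$inn),
        rho_w = matrix(rho0, nrow = s$out, ncol = s$inn),
        mu_b = rep(bias_init, s$out),
        rho_b = rep(rho0, s$out)
      ),
      class = "variational_layer"
    )
  }))
}

#' Closed-form KL divergence between diagonal Gaussians
#'
#' Sums the elementwise `KL(N(mu, sigma^2) || N(prior_mu, prior_sigma^2))`
#' over all entries -- the regulariser of the ELBO for a mean-field
#' Gaussian posterior against a factorised Gaussian prior.
#'
#' @param mu,sigma Posterior means and standard deviations (any shape).
#' @param prior_mu,prior_sigma Prior mean and standard deviation (scalars;
#'   the default is the standard-normal prior).
#' @return Non-negative scalar.
#' @export
kl_gaussian <- function(mu, sigma, prior_mu = 0, prior_sigma = 1) {
  if (any(sigma <= 0)) stop("`sigma` must be positive", call. = FALSE)
  if (prior_sigma <= 0) stop("`prior_sigma` must be positive", call. = FALSE)
  sum(log(prior_sigma / sigma) +
        (sigma^2 + (mu - prior_mu)^2) / (2 * prior_sigma^2) - 0.5)
}

layer_sigmas <- function(layer) {
  list(w = softplus(layer$rho_w), b = softplus(layer$rho_b))
}

# Total KL of all layers against the standard-normal prior.
total_kl <- function(layers) {
  sum(vapply(layers, function(l) {
    s <- layer_sigmas(l)
    kl_gaussian(l$mu_w, s$w) + kl_gaussian(l$mu_b, s$b)
  }, numeric(1)))
}

#' Draw one weight realisation from the variational posterior
#'
#' Reparameterised sampling `w = mu + softplus(rho) * eps` with
#' `eps ~ N(0, 1)`, elementwise for every weight and bias.
#'
#' @param spec A [network_spec()].
#' @param layers Layers from [init_variational_layers()] (or trained).
#' @param seed Optional integer seed for reproducible realisations.
#' @param keep_eps Keep the standard-normal draws (needed for gradients).
#' @return List of per-layer lists with `W`, `b` (and optionally `eps_w`,
#'   `eps_b`).
#' @export
sample_weights <- function(spec, layers, seed = NULL, keep_eps = FALSE) {
  check_layer_shapes(spec, layers)
  with_seed(seed, lapply(layers, function(l) {
    s <- layer_sigmas(l)
    eps_w <- matrix(rnorm(length(l$mu_w)), nrow = nrow(l$mu_w))
    eps_b <- rnorm(length(l$mu_b))
    out <- list(W = l$mu_w + s$w * eps_w, b = l$mu_b + s$b * eps_b)
    if (keep_eps) {
      out$eps_w <- eps_w
      out$eps_b <- eps_b
    }
    out
  }))
}

# Posterior means as a deterministic realisation (the sigma -> 0 limit).
mean_weights <- function(layers) {
  lapply(layers, function(l) list(W = l$mu_w, b = l$mu_b))
}

check_layer_shapes <- function(spec, layers) {
  shapes <- layer_shapes(spec)
  if (length(layers) != length(shapes)) {
    stop("layer list does not match the network spec", call. = FALSE)
  }
  for (nm in names(shapes)) {
    l <- layers[[nm]]
    s <- shapes[[nm]]
    if (is.null(l) || !all(dim(l$mu_w) == c(s$out, s$inn))) {
      stop(sprintf("layer `%s` has the wrong shape (expected %d x %d)",
                   nm, s$out, s$inn), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Deterministic forward pass through one weight realisation
#'
#' Runs a single segment through the network using a fixed weight
#' realisation (from [sample_weights()]). Rectified-linear activations
#' follow every convolution and the first dense layer. Returns the
#' pre-softmax 2-vector (interictal, preictal) and the first convolutional
#' layer's post-activation feature map, which the attention probe consumes.
#'
#' @param spec A [network_spec()].
#' @param weights A weight realisation.
#' @param segment Numeric array `n x 56 x 128` (or an `stft_segment`).
#' @param keep_cache Keep intermediate activations (used by training).
#' @return List with `logits` (length 2), `fmap1` (array
#'   `conv_filters[1] x T1 x F1`), and optionally `cache`.
#' @export
bcnn_forward <- function(spec, weights, segment, keep_cache = FALSE) {
  if (inherits(segment, "stft_segment")) segment <- segment$values
  g <- spec$geom
  expected <- c(spec$n_channels, spec$input_time, spec$input_freq)
  if (!is.numeric(segment) || length(segment) != prod(expected)) {
    stop(sprintf("segment must be a %d x %d x %d array",
                 expected[1], expected[2], expected[3]), call. = FALSE)
  }
  x <- as.numeric(segment)

  al <- spec$activation_slope
  lrelu <- function(y) pmax(y, 0) + al * pmin(y, 0)

  c1 <- conv_forward(x, weights$conv1$W, weights$conv1$b, g$g1)
  a1 <- lrelu(c1$y)
  q1 <- pool_forward(as.numeric(a1), g$p1)

  c2 <- conv_forward(q1$y, weights$conv2$W, weights$conv2$b, g$g2)
  a2 <- lrelu(c2$y)
  q2 <- pool_forward(as.numeric(a2), g$p2)

  c3 <- conv_forward(q2$y, weights$conv3$W, weights$conv3$b, g$g3)
  a3 <- lrelu(c3$y)
  q3 <- pool_forward(as.numeric(a3), g$p3)

  h <- lrelu(as.numeric(weights$dense1$W %*% q3$y) + weights$dense1$b)
  logits <- as.numeric(weights$dense2$W %*% h) + weights$dense2$b

  out <- list(
    logits = logits,
    fmap1 = array(as.numeric(a1), dim = c(spec$conv_filters[1],
                                          g$g1$T_out, g$g1$F_out))
  )
  if (keep_cache) {
    out$cache <- list(xcol1 = c1$xcol, a1 = a1, sel1 = q1$sel,
                      xcol2 = c2$xcol, a2 = a2, sel2 = q2$sel,
                      xcol3 = c3$xcol, a3 = a3, sel3 = q3$sel,
                      z = q3$y, h = h)
  }
  out
}

# Backward pass for one segment. `dlogits` is the gradient of the loss
# w.r.t. the pre-softmax output (after any fusion modulation has been
# chained). Returns per-layer dW / db in the same layout as the weights.
bcnn_backward <- function(spec, weights, cache, dlogits) {
  g <- spec$geom
  al <- spec$activation_slope
  dlrelu <- function(d, a) d * ifelse(a > 0, 1, al)
  dW5 <- dlogits %o% cache$h
  db5 <- dlogits
  dh <- dlrelu(as.numeric(crossprod(weights$dense2$W, dlogits)), cache$h)

  dW4 <- dh %o% cache$z
  db4 <- dh
  dz <- as.numeric(crossprod(weights$dense1$W, dh))

  da3 <- pool_backward(dz, cache$sel3, g$p3$n_in)
  da3 <- dlrelu(matrix(da3, nrow = spec$conv_filters[3]), cache$a3)
  b3 <- conv_backward(da3, weights$conv3$W, cache$xcol3, g$g3)

  da2 <- pool_backward(b3$dx, cache$sel2, g$p2$n_in)
  da2 <- dlrelu(matrix(da2, nrow = spec$conv_filters[2]), cache$a2)
  b2 <- conv_backward(da2, weights$conv2$W, cache$xcol2, g$g2)

  da1 <- pool_backward(b2$dx, cache$sel1, g$p1$n_in)
  da1 <- dlrelu(matrix(da1, nrow = spec$conv_filters[1]), cache$a1)
  b1 <- conv_backward(da1, weights$conv1$W, cache$xcol1, g$g1)

  list(conv1 = list(dW = b1$dW, db = b1$db),
       conv2 = list(dW = b2$dW, db = b2$db),
       conv3 = list(dW = b3$dW, db = b3$db),
       dense1 = list(dW = dW4, db = db4),
       dense2 = list(dW = dW5, db = db5))
}
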