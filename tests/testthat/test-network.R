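test_that("kl_gaussian closed form: identity, unit shift, and MC oracle", {
  expect_equal(kl_gaussian(0, 1), 0)
  expect_equal(kl_gaussian(1, 1), 0.5)
  expect_error(kl_gaussian(0, -1), "positive")

  # Monte-Carlo oracle: E_q[log q - log p] with 1e6 draws
  set.seed(123)
  mu <- runif(3, -0.5, 0.5)
  sigma <- runif(3, 0.3, 1.5)
  n <- 1e6
  for (k in 1:3) {
    z <- rnorm(n, mu[k], sigma[k])
    draws <- dnorm(z, mu[k], sigma[k], log = TRUE) - dnorm(z, log = TRUE)
    se <- sd(draws) / sqrt(n)
    expect_lt(abs(kl_gaussian(mu[k], sigma[k]) - mean(draws)), 3 * se)
  }
})

test_that("network_spec reproduces the reference geometry", {
  sp <- network_spec(19)
  g <- sp$geom
  expect_equal(c(g$g1$T_out, g$g1$F_out), c(26L, 62L))
  expect_equal(c(g$p1$T_out, g$p1$F_out), c(13L, 31L))
  expect_equal(c(g$g2$T_out, g$g2$F_out), c(11L, 29L))
  expect_equal(c(g$p2$T_out, g$p2$F_out), c(5L, 14L))
  expect_equal(c(g$g3$T_out, g$g3$F_out), c(3L, 12L))
  expect_equal(c(g$p3$T_out, g$p3$F_out), c(1L, 6L))
  expect_equal(sp$flat, 128L * 6L)
})

test_that("sample_weights: degenerate posterior, determinism, sampling oracle", {
  sp <- tiny_spec()
  ly <- init_variational_layers(sp, seed = 1L, sigma_init = 1e-9)
  w <- sample_weights(sp, ly, seed = 5L)
  expect_equal(w$conv1$W, ly$conv1$mu_w, tolerance = 1e-6)

  ly <- init_variational_layers(sp, seed = 1L, sigma_init = 0.3)
  w1 <- sample_weights(sp, ly, seed = 7L)
  w2 <- sample_weights(sp, ly, seed = 7L)
  expect_identical(w1, w2)

  # empirical mean/sd of one weight over 1e4 realisations
  draws <- vapply(1:10000, function(i) {
    sample_weights(sp, ly, seed = 1000L + i)$dense2$W[1, 1]
  }, numeric(1))
  mu <- ly$dense2$mu_w[1, 1]
  sigma <- log1p(exp(ly$dense2$rho_w[1, 1]))
  expect_lt(abs(mean(draws) - mu), 3 * sigma / sqrt(10000))
  expect_lt(abs(sd(draws) - sigma), 3 * sigma / sqrt(2 * 10000))
})

test_that("the im2col convolution matches a brute-force oracle", {
  set.seed(11)
  cases <- list(
    list(C = 1L, Tn = 4L, Fn = 5L, kh = 1L, kw = 2L, st = 1L, sw = 2L, Co = 1L),
    list(C = 2L, Tn = 7L, Fn = 9L, kh = 3L, kw = 3L, st = 1L, sw = 1L, Co = 4L),
    list(C = 3L, Tn = 10L, Fn = 12L, kh = 5L, kw = 5L, st = 2L, sw = 2L, Co = 2L)
  )
  for (cs in cases) {
    x <- array(rnorm(cs$C * cs$Tn * cs$Fn), dim = c(cs$C, cs$Tn, cs$Fn))
    W <- matrix(rnorm(cs$Co * cs$C * cs$kh * cs$kw), nrow = cs$Co)
    b <- rnorm(cs$Co)
    g <- seizecast:::im2col_index(cs$C, cs$Tn, cs$Fn, cs$kh, cs$kw, cs$st, cs$sw)
    got <- seizecast:::conv_forward(as.numeric(x), W, b, g)$y
    want <- conv_oracle(x, W, b, cs$kh, cs$kw, cs$st, cs$sw)
    expect_equal(array(as.numeric(got), dim = dim(want)), want,
                 tolerance = 1e-12)
  }
})

test_that("forward pass: zero weights give zero logits; conv layer is linear", {
  sp <- tiny_spec()
  ly <- init_variational_layers(sp, seed = 2L, sigma_init = 1e-9)
  zero <- lapply(ly, function(l) list(W = l$mu_w * 0, b = l$mu_b * 0))
  x <- random_segment(seed = 3L)
  expect_equal(bcnn_forward(sp, zero, x)$logits, c(0, 0))

  # pre-activation linearity of the first convolution (zero bias)
  w <- sample_weights(sp, ly, seed = 4L)
  w$conv1$b <- w$conv1$b * 0
  g <- sp$geom$g1
  y1 <- seizecast:::conv_forward(as.numeric(x), w$conv1$W, w$conv1$b, g)$y
  y2 <- seizecast:::conv_forward(as.numeric(2 * x), w$conv1$W, w$conv1$b, g)$y
  expect_equal(y2, 2 * y1, tolerance = 1e-12)

  expect_error(bcnn_forward(sp, w, array(0, c(2, 56, 128))), "array")
})

test_that("elbo_loss matches an independent cross-entropy implementation", {
  # confident correct predictions, no KL -> near-zero loss
  out <- list(c(10, -10), c(-10, 10))
  expect_lt(elbo_loss(out, c(0, 1))$total, 1e-3)
  # uniform outputs -> log 2 per example
  expect_equal(elbo_loss(list(c(0, 0)), 0)$nll, log(2))
  # arbitrary batch vs straightforward re-implementation
  set.seed(21)
  outs <- lapply(1:7, function(i) rnorm(2))
  labs <- rbinom(7, 1, 0.5)
  ce <- mean(vapply(1:7, function(i) {
    p <- exp(outs[[i]]) / sum(exp(outs[[i]]))
    -log(p[labs[i] + 1])
  }, numeric(1)))
  obj <- elbo_loss(outs, labs, kl_total = 3.2, kl_weight = 0.1)
  expect_equal(obj$nll, ce, tolerance = 1e-12)
  expect_equal(obj$total, ce + 0.32, tolerance = 1e-12)
  expect_error(elbo_loss(list(), integer(0)), "empty")
})

test_that("mc_predict: degenerate posterior collapses, S is honoured, mean converges", {
  sp <- tiny_spec()
  ly <- init_variational_layers(sp, seed = 6L, sigma_init = 1e-9)
  x <- random_segment(seed = 6L)
  s <- mc_predict(sp, ly, x, S = 5L, seed = 1L)
  expect_length(s, 5L)
  expect_lt(diff(range(s)), 1e-6)
  expect_error(mc_predict(sp, ly, x, S = 1L), "at least 2")
  expect_equal(formals(seizecast::mc_predict)$S, 500L)

  ly <- init_variational_layers(sp, seed = 6L, sigma_init = 0.2)
  s <- mc_predict(sp, ly, x, S = 2000L, seed = 2L)
  expect_true(all(s >= 0 & s <= 1))
  expect_lt(abs(mean(s[1:500]) - mean(s)), 3 * sd(s) / sqrt(500))
})

test_that("softmax outputs sum to one across random realisations (property)", {
  sp <- tiny_spec()
  ly <- init_variational_layers(sp, seed = 8L, sigma_init = 0.1)
  x <- random_segment(seed = 8L)
  for (s in 1:5) {
    w <- sample_weights(sp, ly, seed = s)
    p <- seizecast:::softmax2(bcnn_forward(sp, w, x)$logits)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
})

test_that("training requires both classes and records a loss trace", {
  sp <- tiny_spec()
  xs <- lapply(1:6, function(i) abs(random_segment(seed = i)))
  expect_error(train_bcnn(sp, xs, rep(1L, 6)), "both classes")
  m <- train_bcnn(sp, xs, rep(0:1, 3), epochs = 2L, batch_size = 3L,
                  seed = 1L)
  expect_s3_class(m, "bcnn_model")
  expect_length(m$loss_trace, 2L)
  expect_true(all(is.finite(m$loss_trace)))
})

test_that("a large KL weight pins the posterior to the prior", {
  sp <- tiny_spec()
  set.seed(40)
  xs <- lapply(1:12, function(i) {
    off <- if (i %% 2) 0 else 2
    abs(random_segment(seed = 100 + i)) + off
  })
  y <- rep(c(1L, 0L), 6)
  m_free <- train_bcnn(sp, xs, y, epochs = 3L, kl_weight = 0, seed = 2L,
                       kl_anneal = FALSE)
  m_pinned <- train_bcnn(sp, xs, y, epochs = 3L, kl_weight = 100, seed = 2L,
                         kl_anneal = FALSE)
  mean_abs_mu <- function(m) mean(abs(m$layers$dense2$mu_w))
  expect_lt(mean_abs_mu(m_pinned), mean_abs_mu(m_free))
})

test_that("models round-trip through JSON checkpoints, including priors", {
  sp <- tiny_spec()
  xs <- lapply(1:6, function(i) abs(random_segment(seed = i)))
  prior <- fit_auxiliary_prior(c(8.2, 9.1, 7.7, 8.9))
  m <- train_bcnn(sp, xs, rep(0:1, 3), priors = list(prior),
                  aux = rep(c(8, 9), 3), epochs = 1L, seed = 3L)
  path <- tempfile(fileext = ".json")
  save_bcnn(m, path)
  back <- load_bcnn(path)
  expect_equal(back$layers$conv1$mu_w, m$layers$conv1$mu_w)
  expect_equal(back$preproc$center, m$preproc$center)
  expect_s3_class(back$priors[[1]], "auxiliary_prior")
  expect_equal(back$priors[[1]]$bandwidth, prior$bandwidth)
  x <- abs(random_segment(seed = 50L))
  p1 <- predict(m, list(x), aux = 8.5, S = 10L, seed = 4L)
  p2 <- predict(back, list(x), aux = 8.5, S = 10L, seed = 4L)
  expect_equal(p1$mean_score, p2$mean_score, tolerance = 1e-10)
})
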