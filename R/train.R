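#' Negative-ELBO training objective for a batch
#'
#' The loss is the negative evidence lower bound: the expected negative
#' log-likelihood (mean categorical cross-entropy of the softmaxed network
#' outputs against the labels) plus `kl_weight` times the total KL
#' divergence of the weight posterior from its prior. With mini-batch
#' training `kl_weight` is conventionally `1 / n_batches_per_epoch` so one
#' epoch accumulates exactly one full KL term.
#'
#' @param batch_outputs List (or 2-row matrix) of pre-softmax 2-vectors.
#' @param labels Integer vector of 0 (interictal) / 1 (preictal).
#' @param kl_total Total KL divergence of the posterior (see
#'   [kl_gaussian()]).
#' @param kl_weight Non-negative KL scaling.
#' @return List of class `training_objective` with `nll`, `kl`,
#'   `kl_weight`, `total`.
#' @export
elbo_loss <- function(batch_outputs, labels, kl_total = 0, kl_weight = 0) {
  if (is.list(batch_outputs)) {
    if (length(batch_outputs) == 0L) stop("empty batch", call. = FALSE)
    batch_outputs <- do.call(cbind, batch_outputs)
  }
  if (is.null(batch_outputs) || length(batch_outputs) == 0L) {
    stop("empty batch", call. = FALSE)
  }
  if (is.null(dim(batch_outputs))) batch_outputs <- matrix(batch_outputs, nrow = 2L)
  n <- ncol(batch_outputs)
  if (n == 0L) stop("empty batch", call. = FALSE)
  if (length(labels) != n) {
    stop("`labels` must match the number of outputs", call. = FALSE)
  }
  if (kl_total < 0) stop("`kl_total` must be >= 0", call. = FALSE)
  nll <- -mean(vapply(seq_len(n), function(i) {
    log(softmax2(batch_outputs[, i])[labels[i] + 1L])
  }, numeric(1)))
  structure(
    list(nll = nll, kl = kl_total, kl_weight = kl_weight,
         total = nll + kl_weight * kl_total),
    class = "training_objective"
  )
}

adam_state <- function(layers) {
  lapply(layers, function(l) {
    z <- function(x) x * 0 # zeros with the same shape and class
    list(m_mu_w = z(l$mu_w), v_mu_w = z(l$mu_w),
         m_rho_w = z(l$rho_w), v_rho_w = z(l$rho_w),
         m_mu_b = z(l$mu_b), v_mu_b = z(l$mu_b),
         m_rho_b = z(l$rho_b), v_rho_b = z(l$rho_b))
  })
}

adam_update <- function(theta, grad, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  m <- beta1 * m + (1 - beta1) * grad
  v <- beta2 * v + (1 - beta2) * grad^2
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

#' Train the variational network by stochastic ELBO minimisation
#'
#' Mini-batch gradient training of the Gaussian posterior parameters
#' (mu, rho) of every layer, using reparameterised gradients with one
#' weight realisation per mini-batch, adaptive-moment updates, and the
#' closed-form KL gradient. The minority class is oversampled to balance
#' each epoch. Optionally the pre-softmax preictal output is modulated by
#' per-segment auxiliary-evidence fusion factors (the same code path used
#' at prediction time, see [modulate_output()]).
#'
#' @param spec A [network_spec()].
#' @param x List of `n x 56 x 128` arrays (raw STFT magnitudes; see
#'   `log_transform`).
#' @param labels Integer vector of 0 (interictal) / 1 (preictal).
#' @param priors Optional list of [fit_auxiliary_prior()] objects enabling
#'   fusion during training.
#' @param aux Optional data frame (or matrix) of auxiliary values aligned
#'   with `priors` columns and `x` rows (e.g. a single `clock_hour`
#'   column).
#' @param epochs,batch_size,lr Optimisation controls.
#' @param kl_weight KL scaling; `NULL` (default) uses
#'   `1 / n_batches_per_epoch`.
#' @param kl_anneal If `TRUE`, ramp the KL weight linearly from 0 to
#'   `kl_weight` over the first half of training (the standard
#'   stochastic-VI warm-up); off by default, as it brings no benefit at
#'   desk scale.
#' @param sigma_init Initial posterior standard deviation.
#' @param log_transform Apply `log1p` to inputs before standardising.
#' @param seed Integer seed controlling initialisation, batching, and
#'   weight sampling.
#' @param restarts Number of random initialisations tried (multi-start
#'   optimisation). Each restart derives its seed from `seed`; the run
#'   with the lowest posterior-mean training cross-entropy is kept.
#'   Deterministic given `seed`.
#' @param verbose Print per-epoch losses.
#' @return Object of class `bcnn_model`: `spec`, `layers`, `preproc`
#'   (input transform parameters), `priors`, `loss_trace` (per-epoch mean
#'   total loss), `nll_trace`, `config`.
#' @export
train_bcnn <- function(spec, x, labels, priors = NULL, aux = NULL,
                       epochs = 10L, batch_size = 32L, lr = 3e-3,
                       kl_weight = NULL, kl_anneal = FALSE, sigma_init = 0.02,
                       log_transform = TRUE, seed = 1L, restarts = 1L,
                       verbose = FALSE) {
  stopifnot(inherits(spec, "network_spec"))
  n <- length(x)
  labels <- as.integer(labels)
  if (length(labels) != n) stop("`labels` must match `x`", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }

  # fusion factors, fixed per segment for the whole run
  factors <- rep(1, n)
  if (!is.null(priors)) {
    if (is.null(aux)) stop("`aux` values required when `priors` given", call. = FALSE)
    aux <- as.matrix(aux)
    factors <- vapply(seq_len(n), function(i) {
      fusion_factor(priors, aux[i, ])$value
    }, numeric(1))
  }

  # input transform: optional log1p, then global standardisation
  xs <- lapply(x, function(a) if (log_transform) log1p(a) else a)
  if (!all(vapply(xs, function(a) all(is.finite(a)), logical(1)))) {
    stop(paste("non-finite values in the transformed inputs;",
               "log_transform = TRUE requires non-negative inputs"),
         call. = FALSE)
  }
  center <- mean(vapply(xs, mean, numeric(1)))
  scale <- sqrt(mean(vapply(xs, function(a) mean((a - center)^2), numeric(1))))
  if (scale == 0) scale <- 1
  xs <- lapply(xs, function(a) (a - center) / scale)

  idx0 <- which(labels == 0L)
  idx1 <- which(labels == 1L)
  n_per_epoch <- 2L * max(length(idx0), length(idx1))
  n_batches <- max(1L, ceiling(n_per_epoch / batch_size))
  klw_final <- kl_weight %||% (1 / n_batches)
  total_steps <- n_batches * epochs

  run_once <- function(run_seed) {
  layers <- init_variational_layers(spec, seed = run_seed,
                                    sigma_init = sigma_init)
  opt <- adam_state(layers)
  nms <- names(layers)

  loss_trace <- numeric(0)
  nll_trace <- numeric(0)
  t_step <- 0L
  with_seed(run_seed, {
    for (ep in seq_len(epochs)) {
      # balance classes by oversampling the minority
      n_major <- max(length(idx0), length(idx1))
      over <- function(ii) if (length(ii) == n_major) ii else
        sample(ii, n_major, replace = TRUE)
      order_ep <- sample(c(over(idx0), over(idx1)))
      ep_losses <- numeric(0)
      ep_nlls <- numeric(0)
      for (bstart in seq(1L, length(order_ep), by = batch_size)) {
        bidx <- order_ep[bstart:min(bstart + batch_size - 1L, length(order_ep))]
        t_step <- t_step + 1L
        klw <- if (kl_anneal) {
          klw_final * min(1, t_step / (0.5 * total_steps))
        } else {
          klw_final
        }
        w <- sample_weights(spec, layers, keep_eps = TRUE)

        grads <- NULL
        outputs <- matrix(0, nrow = 2L, ncol = length(bidx))
        for (j in seq_along(bidx)) {
          i <- bidx[j]
          fw <- bcnn_forward(spec, w, xs[[i]], keep_cache = TRUE)
          lg <- modulate_output(fw$logits, factors[i])
          outputs[, j] <- lg
          p <- softmax2(lg)
          dlog <- p
          dlog[labels[i] + 1L] <- dlog[labels[i] + 1L] - 1
          dlog <- dlog / length(bidx)
          dlog[2L] <- dlog[2L] * factors[i] # chain through the modulator
          gi <- bcnn_backward(spec, w, fw$cache, dlog)
          if (is.null(grads)) {
            grads <- gi
          } else {
            for (nm in nms) {
              grads[[nm]]$dW <- grads[[nm]]$dW + gi[[nm]]$dW
              grads[[nm]]$db <- grads[[nm]]$db + gi[[nm]]$db
            }
          }
        }

        kl_now <- total_kl(layers)
        obj <- elbo_loss(outputs, labels[bidx], kl_now, klw)
        if (!is.finite(obj$total)) {
          stop("training diverged (non-finite loss); lower `lr` or raise `sigma_init`",
               call. = FALSE)
        }
        ep_losses <- c(ep_losses, obj$total)
        ep_nlls <- c(ep_nlls, obj$nll)

        for (nm in nms) {
          l <- layers[[nm]]
          sw <- softplus(l$rho_w); sb <- softplus(l$rho_b)
          dsig_w <- stats::plogis(l$rho_w); dsig_b <- stats::plogis(l$rho_b)
          # reparameterisation + closed-form KL gradients
          dmu_w <- grads[[nm]]$dW + klw * l$mu_w
          drho_w <- grads[[nm]]$dW * w[[nm]]$eps_w * dsig_w +
            klw * (sw - 1 / sw) * dsig_w
          dmu_b <- grads[[nm]]$db + klw * l$mu_b
          drho_b <- grads[[nm]]$db * w[[nm]]$eps_b * dsig_b +
            klw * (sb - 1 / sb) * dsig_b

          u <- adam_update(l$mu_w, dmu_w, opt[[nm]]$m_mu_w, opt[[nm]]$v_mu_w, lr, t_step)
          layers[[nm]]$mu_w <- u$theta; opt[[nm]]$m_mu_w <- u$m; opt[[nm]]$v_mu_w <- u$v
          u <- adam_update(l$rho_w, drho_w, opt[[nm]]$m_rho_w, opt[[nm]]$v_rho_w, lr, t_step)
          layers[[nm]]$rho_w <- u$theta; opt[[nm]]$m_rho_w <- u$m; opt[[nm]]$v_rho_w <- u$v
          u <- adam_update(l$mu_b, dmu_b, opt[[nm]]$m_mu_b, opt[[nm]]$v_mu_b, lr, t_step)
          layers[[nm]]$mu_b <- u$theta; opt[[nm]]$m_mu_b <- u$m; opt[[nm]]$v_mu_b <- u$v
          u <- adam_update(l$rho_b, drho_b, opt[[nm]]$m_rho_b, opt[[nm]]$v_rho_b, lr, t_step)
          layers[[nm]]$rho_b <- u$theta; opt[[nm]]$m_rho_b <- u$m; opt[[nm]]$v_rho_b <- u$v
        }
      }
      loss_trace <- c(loss_trace, mean(ep_losses))
      nll_trace <- c(nll_trace, mean(ep_nlls))
      if (verbose) {
        message(sprintf("epoch %d/%d  loss %.4f  nll %.4f",
                        ep, epochs, loss_trace[ep], nll_trace[ep]))
      }
    }
  })
  list(layers = layers, loss_trace = loss_trace, nll_trace = nll_trace)
  }

  runs <- list()
  for (r in seq_len(max(1L, restarts))) {
    run_seed <- as.integer((seed + 7919 * (r - 1L)) %% .Machine$integer.max)
    if (verbose && restarts > 1L) message(sprintf("restart %d", r))
    runs[[r]] <- run_once(run_seed)
    runs[[r]]$seed <- run_seed
  }
  # select the restart by deterministic posterior-mean training
  # cross-entropy: the per-batch sampled NLL is too noisy to rank runs
  mean_ce <- function(ru) {
    w <- mean_weights(ru$layers)
    mean(vapply(seq_len(n), function(i) {
      lg <- modulate_output(bcnn_forward(spec, w, xs[[i]])$logits, factors[i])
      -log(softmax2(lg)[labels[i] + 1L])
    }, numeric(1)))
  }
  sel_ce <- vapply(runs, mean_ce, numeric(1))
  best <- runs[[which.min(sel_ce)]]

  structure(
    list(spec = spec, layers = best$layers,
         preproc = list(log_transform = log_transform,
                        center = center, scale = scale),
         priors = priors, loss_trace = best$loss_trace,
         nll_trace = best$nll_trace,
         config = list(epochs = epochs, batch_size = batch_size, lr = lr,
                       kl_weight = klw_final, kl_anneal = kl_anneal,
                       sigma_init = sigma_init, seed = seed,
                       restarts = restarts, selected_seed = best$seed)),
    class = "bcnn_model"
  )
}

#' @export
print.bcnn_model <- function(x, ...) {
  cat(sprintf("<bcnn_model> trained %d epochs, final loss %.4f%s\n",
              length(x$loss_trace), tail(x$loss_trace, 1),
              if (is.null(x$priors)) "" else ", with auxiliary fusion"))
  invisible(x)
}

apply_preproc <- function(model, segment) {
  if (inherits(segment, "stft_segment")) segment <- segment$values
  if (model$preproc$log_transform) segment <- log1p(segment)
  (segment - model$preproc$center) / model$preproc$scale
}

#' Monte-Carlo predictive sampling for one segment
#'
#' Feeds the same input forward `S` times, each pass through an
#' independent weight realisation drawn from the posterior, and collects
#' the post-softmax preictal probabilities. These samples are the basis of
#' the uncertainty level ([uncertainty_level()]).
#'
#' @param spec A [network_spec()].
#' @param layers Trained variational layers.
#' @param segment One preprocessed input (already transformed; use
#'   [predict.bcnn_model()] for end-to-end prediction).
#' @param S Number of forward passes (the reference protocol uses 500).
#' @param seed Integer seed.
#' @param factor Fusion factor applied to the preictal pre-softmax output
#'   (1 = no fusion).
#' @return Object of class `prediction_samples`: numeric vector of `S`
#'   scores in `[0, 1]`.
#' @export
mc_predict <- function(spec, layers, segment, S = 500L, seed = NULL,
                       factor = 1) {
  if (S < 2L) stop("`S` must be at least 2", call. = FALSE)
  scores <- with_seed(seed, vapply(seq_len(S), function(s) {
    w <- sample_weights(spec, layers)
    lg <- modulate_output(bcnn_forward(spec, w, segment)$logits, factor)
    softmax2(lg)[2L]
  }, numeric(1)))
  structure(scores, class = "prediction_samples")
}

#' Predict seizure-risk scores with uncertainty for new segments
#'
#' @param object A trained [train_bcnn()] model.
#' @param newdata List of raw `n x 56 x 128` arrays.
#' @param aux Optional auxiliary values (e.g. clock hours) enabling fusion
#'   when the model holds priors, or when `priors` is supplied.
#' @param priors Override the model's stored auxiliary priors (use `NULL`
#'   with `aux = NULL` to disable fusion).
#' @param S Monte-Carlo samples per segment.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return Data frame with one row per segment: `mean_score`, `std_score`,
#'   `uncertainty`, `uncertainty_display`.
#' @export
predict.bcnn_model <- function(object, newdata, aux = NULL,
                               priors = object$priors, S = 100L,
                               seed = NULL, ...) {
  n <- length(newdata)
  factors <- rep(1, n)
  if (!is.null(priors) && !is.null(aux)) {
    aux <- as.matrix(aux)
    factors <- vapply(seq_len(n), function(i) {
      fusion_factor(priors, aux[i, ])$value
    }, numeric(1))
  }
  rows <- with_seed(seed, lapply(seq_len(n), function(i) {
    xs <- apply_preproc(object, newdata[[i]])
    samples <- mc_predict(object$spec, object$layers, xs, S = S,
                          factor = factors[i])
    est <- uncertainty_level(samples)
    data.frame(mean_score = est$mean_score, std_score = est$std_score,
               uncertainty = est$level,
               uncertainty_display = est$display_level)
  }))
  do.call(rbind, rows)
}
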