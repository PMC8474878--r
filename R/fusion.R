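#' Fit a Gaussian-KDE auxiliary prior from event-time observations
#'
#' Estimates `p(d | z')`, the density of an auxiliary variable `d` at
#' seizure occurrence, with a Gaussian kernel density estimate using
#' Scott's bandwidth (`n^(-1/5) * sd`), all observations equally weighted.
#' For the circular 24-hour domain the estimate wraps around midnight by
#' evaluating replicas of the data at -24 and +24 h, and the baseline
#' density `p(d)` is uniform at 1/24 per hour. For a linear domain the
#' baseline is uniform over the stated bounds.
#'
#' @param values Numeric observations of the auxiliary variable at seizure
#'   onsets (e.g. clock hours); at least 2, with positive spread.
#' @param domain `"circular24"` for hour-of-day, or a numeric
#'   `c(lower, upper)` for a bounded linear variable.
#' @param bandwidth Optional bandwidth override (required if the data have
#'   zero variance).
#' @return Object of class `auxiliary_prior`.
#' @export
fit_auxiliary_prior <- function(values, domain = "circular24",
                                bandwidth = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("need at least 2 observations to fit a prior", call. = FALSE)
  }
  circular <- identical(domain, "circular24")
  if (circular) {
    values <- values %% 24
  } else {
    domain <- as.numeric(domain)
    if (length(domain) != 2L || domain[1] >= domain[2]) {
      stop("`domain` must be \"circular24\" or c(lower, upper)", call. = FALSE)
    }
  }
  if (is.null(bandwidth)) {
    s <- sd(values)
    if (s == 0) {
      stop("observations have zero variance; supply `bandwidth` explicitly",
           call. = FALSE)
    }
    bandwidth <- length(values)^(-1 / 5) * s # Scott's rule, d = 1
  }
  stopifnot_scalar(bandwidth, "bandwidth", positive = TRUE)
  structure(
    list(values = values, bandwidth = bandwidth,
         domain = if (circular) "circular24" else domain,
         circular = circular),
    class = "auxiliary_prior"
  )
}

# Density of the fitted KDE at points v (vectorised).
kde_density <- function(prior, v) {
  obs <- prior$values
  if (prior$circular) {
    v <- v %% 24
    obs <- c(obs - 24, obs, obs + 24) # replica wrapping at +/- one period
    vapply(v, function(vi) {
      sum(dnorm(vi, mean = obs, sd = prior$bandwidth)) / length(prior$values)
    }, numeric(1))
  } else {
    vapply(v, function(vi) {
      mean(dnorm(vi, mean = obs, sd = prior$bandwidth))
    }, numeric(1))
  }
}

#' Evaluate an auxiliary prior at a value
#'
#' Returns both the seizure-conditional KDE density `p(v | z')` and the
#' uniform baseline `p(v)` (1/24 per hour on the circular domain). The
#' conditional density is floored at `floor_eps` so a zero estimated
#' density can never entirely veto the EEG evidence.
#'
#' @param prior An [fit_auxiliary_prior()] object.
#' @param v Auxiliary value(s); hours are reduced modulo 24 on the
#'   circular domain.
#' @param floor_eps Lower bound applied to the conditional density.
#' @return List with numeric vectors `conditional` and `baseline`.
#' @export
evaluate_prior <- function(prior, v, floor_eps = 1e-6) {
  stopifnot(inherits(prior, "auxiliary_prior"))
  cond <- pmax(kde_density(prior, v), floor_eps)
  base <- if (prior$circular) {
    rep(1 / 24, length(v))
  } else {
    rep(1 / diff(prior$domain), length(v))
  }
  list(conditional = cond, baseline = base)
}

#' Multiplicative evidence-fusion factor from auxiliary signals
#'
#' Under the assumption that the EEG and all auxiliary signals are
#' mutually independent, the posterior seizure probability factorises into
#' the network output times the product of per-signal likelihood ratios
#' `p(d_i | z') / p(d_i)`. This function computes that product; an empty
#' signal list yields 1, i.e. fusion disabled.
#'
#' @param priors List of [fit_auxiliary_prior()] objects (possibly empty).
#' @param values Numeric vector of auxiliary observations, aligned with
#'   `priors`.
#' @return Object of class `fusion_factor`: list with `value` (positive
#'   scalar) and `components` (per-signal ratios).
#' @export
fusion_factor <- function(priors, values) {
  if (inherits(priors, "auxiliary_prior")) priors <- list(priors)
  if (length(priors) != length(values)) {
    stop("`priors` and `values` must have the same length", call. = FALSE)
  }
  components <- vapply(seq_along(priors), function(i) {
    e <- evaluate_prior(priors[[i]], values[i])
    e$conditional / e$baseline
  }, numeric(1))
  structure(list(value = prod(components), components = components),
            class = "fusion_factor")
}

#' Modulate the network's pre-softmax output by a fusion factor
#'
#' Multiplies the preictal component of the final fully-connected layer's
#' output by the fusion factor, leaving the interictal component
#' untouched, before the softmax. (Scaling both components by the same
#' factor would cancel in the softmax, so the modulation is necessarily
#' asymmetric.) The same code path is used during training and inference.
#'
#' @param outputs Pre-softmax 2-vector (interictal, preictal).
#' @param factor A [fusion_factor()] or a positive scalar.
#' @param log_domain If `TRUE`, add `log(factor)` to the preictal output
#'   instead of multiplying -- the Bayes-composition reading; the literal
#'   multiplicative rule is the default.
#' @return Modulated 2-vector.
#' @export
modulate_output <- function(outputs, factor, log_domain = FALSE) {
  f <- if (inherits(factor, "fusion_factor")) factor$value else factor
  if (!is.finite(f)) stop("fusion factor must be finite", call. = FALSE)
  if (length(outputs) != 2L || any(!is.finite(outputs))) {
    stop("`outputs` must be a finite 2-vector", call. = FALSE)
  }
  if (log_domain) {
    outputs[2L] <- outputs[2L] + log(f)
  } else {
    outputs[2L] <- outputs[2L] * f
  }
  outputs
}

#' Serialise / restore an auxiliary prior as JSON
#'
#' Stores the observations, bandwidth, and domain descriptor so fitted
#' priors are portable across sessions.
#'
#' @param prior An [fit_auxiliary_prior()] object.
#' @param path File path.
#' @return `save_prior` returns `path` invisibly; `load_prior` returns the
#'   restored prior.
#' @export
save_prior <- function(prior, path) {
  stopifnot(inherits(prior, "auxiliary_prior"))
  jsonlite::write_json(
    list(values = prior$values, bandwidth = prior$bandwidth,
         domain = prior$domain),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname save_prior
#' @export
load_prior <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit_auxiliary_prior(obj$values, domain = obj$domain,
                      bandwidth = obj$bandwidth)
}
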