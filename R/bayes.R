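## Bayesian machinery for the GED shape parameter under an exponential
## prior: posterior density, Bayes estimators under squared-error and
## LINEX loss, balanced (BSE / BLINEX) estimators mixing in the MLE, and
## empirical-Bayes estimation of the prior rate from the marginal model.

#' Exponential prior specification
#'
#' Prior density `b * exp(-b * theta)` on the GED shape.
#'
#' @param b positive prior rate; the prior mean is `1/b`.
#' @export
prior_spec <- function(b) {
  stopifnot(length(b) == 1L, is.finite(b))
  if (b <= 0) stop("'b' must be > 0")
  structure(list(b = b), class = "prior_spec")
}

#' Loss function configuration
#'
#' @param family one of `"SE"`, `"LINEX"`, `"BSE"`, `"BLINEX"`.
#' @param c LINEX/BLINEX asymmetry parameter (nonzero; positive values
#'   penalize overestimation more).
#' @param delta balanced-loss weight on the target (MLE) component,
#'   in `[0, 1]`; used by the balanced families only.
#' @export
loss_config <- function(family = c("SE", "LINEX", "BSE", "BLINEX"),
                        c = NULL, delta = NULL) {
  family <- match.arg(family)
  if (family %in% c("LINEX", "BLINEX")) {
    if (is.null(c) || !is.finite(c) || c == 0)
      stop("'c' must be a nonzero number for LINEX-type losses")
  }
  if (family %in% c("BSE", "BLINEX")) {
    if (is.null(delta)) delta <- 0.5
    if (delta < 0 || delta > 1) stop("'delta' must be in [0, 1]")
  }
  structure(list(family = family, c = c, delta = delta), class = "loss_config")
}

## ---- posterior evaluation -------------------------------------------------

## quadrature against the permanent-form posterior: returns the
## normalizing constant \int L(theta) e^{-b theta} dtheta, the posterior
## mean and (optionally) E[e^{-c theta} | z] for each c.
.post_quad <- function(sample, lambda, b, c = NULL, size_model = NULL,
                       rel.tol = 1e-10) {
  lp <- function(th) vapply(th, function(t)
    loglik_theta(t, sample, lambda, size_model) - b * t, numeric(1))
  shift <- .gridded_max(lp, lower = 1e-8, upper = 1e3)$objective
  f <- function(th) exp(lp(th) - shift)
  quad <- function(g) stats::integrate(function(th) g(th) * f(th), 0, Inf,
                                       rel.tol = rel.tol, abs.tol = 0,
                                       subdivisions = 400L)$value
  z <- quad(function(th) rep(1, length(th)))
  if (!is.finite(z) || z <= 0) stop("posterior normalization failed")
  out <- list(norm_const = z * exp(shift), mean = quad(identity) / z)
  if (!is.null(c))
    out$linex <- vapply(c, function(cc) {
      ## keep the tilt inside the exponent: exp(-cc*th) alone overflows
      ## for negative cc where the posterior factor is already zero
      stats::integrate(function(th) exp(lp(th) - cc * th - shift), 0, Inf,
                       rel.tol = rel.tol, abs.tol = 0,
                       subdivisions = 400L)$value / z
    }, numeric(1))
  out
}

## closed form from the exact (complement-form) term expansion:
## norm = sum coef Gamma(eta+1) / (b+W)^(eta+1), etc.
.post_closed <- function(sample, lambda, b, c = NULL, size_model = NULL) {
  tt <- .lik_termsets(sample, lambda, size_model, sf_form = "complement")
  S <- function(shift_b, extra_pow = 0) {
    sum(tt$coef * exp(lgamma(tt$eta + 1 + extra_pow) -
                        (tt$eta + 1 + extra_pow) * log(b + shift_b + tt$W)))
  }
  z <- S(0)
  if (!is.finite(z) || z <= 0) stop("closed-form normalization failed")
  out <- list(norm_const = z, mean = S(0, extra_pow = 1) / z)
  if (!is.null(c)) out$linex <- vapply(c, function(cc) S(cc) / z, numeric(1))
  out
}

#' Posterior summary quantities
#'
#' Normalizing constant \eqn{\int_0^\infty \zeta(\theta) e^{-b\theta}
#' d\theta}, posterior mean, and optionally the LINEX transform
#' \eqn{E(e^{-c\theta} \mid z)}.
#'
#' @inheritParams likelihood_series
#' @param prior a [prior_spec()].
#' @param c optional vector of LINEX asymmetry values.
#' @param method `"quadrature"` (canonical; adaptive integration against
#'   the permanent-form posterior) or `"closed_form"` (exact
#'   gamma-integral series from the term expansion; used as the
#'   cross-check route).
#' @return A list with `norm_const`, `mean`, optionally `linex`, and
#'   `method`.
#' @export
posterior_summary <- function(sample, lambda, prior, c = NULL,
                              size_model = NULL,
                              method = c("quadrature", "closed_form")) {
  stopifnot(inherits(sample, "censored_omelrrss"), inherits(prior, "prior_spec"))
  method <- match.arg(method)
  out <- if (method == "quadrature")
    .post_quad(sample, lambda, prior$b, c, size_model)
  else .post_closed(sample, lambda, prior$b, c, size_model)
  out$method <- method
  out
}

#' Posterior density of the shape parameter
#'
#' Likelihood times the exponential prior, normalized.
#'
#' @inheritParams posterior_summary
#' @param theta evaluation points (vectorized).
#' @export
posterior_density <- function(theta, sample, lambda, prior,
                              size_model = NULL,
                              method = c("quadrature", "closed_form")) {
  method <- match.arg(method)
  b <- prior$b
  if (method == "quadrature") {
    z <- .post_quad(sample, lambda, b, size_model = size_model)$norm_const
    vapply(theta, function(th)
      exp(loglik_theta(th, sample, lambda, size_model) - b * th) / z,
      numeric(1))
  } else {
    tt <- .lik_termsets(sample, lambda, size_model, sf_form = "complement")
    z <- .post_closed(sample, lambda, b, size_model = size_model)$norm_const
    vapply(theta, function(th)
      sum(tt$coef * th^tt$eta * exp(-(b + tt$W) * th)) / z, numeric(1))
  }
}

#' Bayes estimators under SE and LINEX loss
#'
#' Squared-error loss gives the posterior mean; LINEX loss with
#' asymmetry `c` gives `-(1/c) * log E(e^{-c theta} | z)`.
#'
#' @inheritParams posterior_summary
#' @param loss a [loss_config()] with family `"SE"` or `"LINEX"`.
#' @return The point estimate (a single number).
#' @export
bayes_estimate <- function(sample, lambda, prior, loss = loss_config("SE"),
                           size_model = NULL,
                           method = c("quadrature", "closed_form")) {
  stopifnot(inherits(loss, "loss_config"))
  if (!loss$family %in% c("SE", "LINEX"))
    stop("use balanced_bayes_estimate() for balanced losses")
  ps <- posterior_summary(sample, lambda, prior,
                          c = if (loss$family == "LINEX") loss$c,
                          size_model = size_model, method = match.arg(method))
  if (loss$family == "SE") ps$mean else -log(ps$linex) / loss$c
}

#' Balanced Bayes estimators (BSE / BLINEX)
#'
#' BSE: `delta * mle + (1 - delta) * posterior mean`.  BLINEX:
#' `-(1/c) * log(delta * exp(-c * mle) + (1 - delta) * E(e^{-c theta}|z))`.
#'
#' @inheritParams bayes_estimate
#' @param loss a [loss_config()] with family `"BSE"` or `"BLINEX"`.
#' @param mle the maximum-likelihood estimate of theta; computed via
#'   [mle_theta()] when omitted.
#' @export
balanced_bayes_estimate <- function(sample, lambda, prior, loss, mle = NULL,
                                    size_model = NULL,
                                    method = c("quadrature", "closed_form")) {
  stopifnot(inherits(loss, "loss_config"))
  if (!loss$family %in% c("BSE", "BLINEX"))
    stop("'loss' must be a balanced family (BSE or BLINEX)")
  if (is.null(mle)) mle <- mle_theta(sample, lambda, size_model)$theta
  d <- loss$delta
  if (d == 1) return(mle)
  ps <- posterior_summary(sample, lambda, prior,
                          c = if (loss$family == "BLINEX") loss$c,
                          size_model = size_model, method = match.arg(method))
  if (loss$family == "BSE") d * mle + (1 - d) * ps$mean
  else -log(d * exp(-loss$c * mle) + (1 - d) * ps$linex) / loss$c
}

#' Empirical-Bayes estimate of the prior rate
#'
#' Maximizes, over `b`, the censored OMELRRSS likelihood in which the
#' GED base model is replaced by its theta-marginal under the
#' exponential prior: with `t(w) = -log(1 - e^{-lambda w})`, the
#' marginal base CDF is `b / (b + t(w))` and the marginal base density
#' `lambda e^{-lambda w} e^{t(w)} b / (b + t(w))^2`.  One-dimensional
#' bounded search on `(1e-6, 1e3)`.
#'
#' @inheritParams posterior_summary
#' @return A list with `b` (the estimate), `loglik`, and `boundary`
#'   (`TRUE`, with a warning, when the maximum sits at the search
#'   boundary).
#' @export
estimate_hyperparameter_b <- function(sample, lambda, size_model = NULL) {
  stopifnot(inherits(sample, "censored_omelrrss"))
  cs <- .as_ascending(sample)
  sch <- cs$scheme
  f <- function(b) {
    base <- .base_marginal(b, lambda)
    if (is.null(size_model))
      return(.loglik_fixed(NA, lambda, cs$window, cs$r, cs$s, sch$n,
                           sch$record_indices, sch$k, base = base))
    supp <- .size_support(size_model, cs$s)
    w <- sample_size_pmf(supp, size_model, truncate_at = cs$s)
    ll <- vapply(seq_along(supp), function(j) {
      sch_n <- .truncate_scheme(sch, supp[j])
      .loglik_fixed(NA, lambda, cs$window, cs$r, cs$s, supp[j],
                    sch_n$record_indices, sch_n$k, base = base)
    }, numeric(1))
    m <- max(ll + log(w))
    if (!is.finite(m)) return(-Inf)
    m + log(sum(exp(ll + log(w) - m)))
  }
  opt <- .gridded_max(function(b) vapply(b, f, numeric(1)),
                      lower = 1e-6, upper = 1e3, tol = 1e-8)
  boundary <- opt$maximum < 1e-4 || opt$maximum > 990
  if (boundary) warning("hyperparameter estimate at the search boundary")
  list(b = opt$maximum, loglik = opt$objective, boundary = boundary)
}

#' Empirical-Bayes balanced estimators
#'
#' [balanced_bayes_estimate()] with the prior rate replaced by its
#' marginal-likelihood estimate (or a user-supplied value).
#'
#' @inheritParams balanced_bayes_estimate
#' @param b_tilde estimated prior rate; computed via
#'   [estimate_hyperparameter_b()] when omitted.
#' @export
empirical_bayes_estimate <- function(sample, lambda, loss, b_tilde = NULL,
                                     mle = NULL, size_model = NULL,
                                     method = c("quadrature", "closed_form")) {
  if (is.null(b_tilde))
    b_tilde <- estimate_hyperparameter_b(sample, lambda, size_model)$b
  balanced_bayes_estimate(sample, lambda, prior_spec(b_tilde), loss,
                          mle = mle, size_model = size_model,
                          method = match.arg(method))
}
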