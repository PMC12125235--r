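## Generalized exponential distribution (GED) and the marginal
## distributions of i-th lower k-record values drawn from it.
##
## Throughout, t(w) = -log(1 - exp(-lambda*w)) is the decreasing
## transform that sends a GED variate to the positive half-line; the key
## identity used everywhere in this package is that if W is the i-th
## lower k-record of an iid GED(theta, lambda) stream then
## k*theta*t(W) ~ Gamma(shape = i, rate = 1) exactly.

#' GED parameter container
#'
#' Validates and stores the shape and scale (rate) parameters of the
#' generalized exponential distribution with CDF
#' \eqn{G(w) = (1 - e^{-\lambda w})^\theta}.
#'
#' @param theta positive shape parameter (dimensionless).
#' @param lambda positive scale/rate parameter (per unit time).
#' @return An object of class `"ged_params"`.
#' @examples
#' p <- ged_params(2, 1.5)
#' @export
ged_params <- function(theta, lambda) {
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta),
            is.numeric(lambda), length(lambda) == 1L, is.finite(lambda))
  if (theta <= 0) stop("'theta' must be > 0")
  if (lambda <= 0) stop("'lambda' must be > 0")
  structure(list(theta = theta, lambda = lambda), class = "ged_params")
}

#' @export
print.ged_params <- function(x, ...) {
  cat(sprintf("GED(theta = %g, lambda = %g)\n", x$theta, x$lambda))
  invisible(x)
}

#' Record index specification
#'
#' @param i record index (which lower k-record in the sequence), `i >= 1`.
#' @param k record level, `k >= 1`; `k = 1` gives ordinary lower records.
#' @return An object of class `"record_spec"`.
#' @export
record_spec <- function(i, k) {
  stopifnot(length(i) == 1L, length(k) == 1L)
  if (!is.finite(i) || i < 1 || i != round(i)) stop("'i' must be a positive integer")
  if (!is.finite(k) || k < 1 || k != round(k)) stop("'k' must be a positive integer")
  structure(list(i = as.integer(i), k = as.integer(k)), class = "record_spec")
}

## t(w) = -log(1 - e^{-lambda w}) and its inverse; two-branch log1mexp
## evaluation keeps full precision at both ends (expm1 branch for small
## arguments, log1p branch for large ones).
.log1mexp <- function(x) ifelse(x > log(2), log1p(-exp(-x)), log(-expm1(-x)))
.tfun <- function(w, lambda) -.log1mexp(lambda * w)
.tinv <- function(u, lambda) -.log1mexp(u) / lambda

.check_w <- function(w, positive = FALSE) {
  if (any(!is.finite(w) & !is.nan(w) & w != Inf)) stop("non-finite 'w'")
  if (positive) { if (any(w <= 0)) stop("'w' must be > 0") }
  else if (any(w < 0)) stop("'w' must be >= 0")
}

#' GED density, distribution, quantile, hazard and random generation
#'
#' `dged` is \eqn{\theta\lambda e^{-\lambda w}(1-e^{-\lambda w})^{\theta-1}},
#' `pged` is \eqn{(1-e^{-\lambda w})^\theta}, `qged` inverts it in closed
#' form, `hged` is the hazard rate `dged / (1 - pged)` (decreasing for
#' `theta < 1`, constant `= lambda` for `theta = 1`, increasing for
#' `theta > 1`), and `rged` draws by inverse-CDF sampling.
#'
#' @param w vector of nonnegative lifetimes (strictly positive for `hged`).
#' @param p probabilities in (0, 1).
#' @param n number of draws.
#' @param theta,lambda GED parameters, see [ged_params()].
#' @param log logical; return the log density?
#' @return Numeric vector.
#' @examples
#' dged(0.5, theta = 1, lambda = 2)     # exponential special case
#' qged(pged(1.3, 2, 1), 2, 1)          # round trip
#' @export
dged <- function(w, theta, lambda, log = FALSE) {
  ged_params(theta, lambda); .check_w(w)
  lg <- log(theta) + log(lambda) - lambda * w + (theta - 1) * log1p(-exp(-lambda * w))
  lg[w == 0] <- if (theta > 1) -Inf else if (theta == 1) log(theta * lambda) else Inf
  if (log) lg else exp(lg)
}

#' @rdname dged
#' @export
pged <- function(w, theta, lambda) {
  ged_params(theta, lambda); .check_w(w)
  exp(theta * log1p(-exp(-lambda * w)))
}

#' @rdname dged
#' @export
qged <- function(p, theta, lambda) {
  ged_params(theta, lambda)
  if (any(p <= 0 | p >= 1)) stop("'p' must be in (0, 1)")
  -log1p(-exp(log(p) / theta)) / lambda
}

#' @rdname dged
#' @export
hged <- function(w, theta, lambda) {
  ged_params(theta, lambda); .check_w(w, positive = TRUE)
  dged(w, theta, lambda) / (1 - pged(w, theta, lambda))
}

#' @rdname dged
#' @export
rged <- function(n, theta, lambda) {
  qged(stats::runif(n), theta, lambda)
}

#' Marginal distribution of the i-th lower k-record of a GED stream
#'
#' Density, CDF and survival function of the i-th lower k-record value
#' in an iid GED(theta, lambda) sequence.  The density is
#' \deqn{f_{(i)}(w) = \frac{k^i}{(i-1)!}(-\log G(w))^{i-1} G(w)^{k-1} g(w),}
#' and, writing \eqn{u = -k\log G(w)}, the CDF equals the upper Gamma
#' tail \eqn{P(\mathrm{Gamma}(i,1) > u)} = \eqn{G^k\sum_{v<i} u^v/v!},
#' a finite sum; the survival function is its complement (so the two
#' always sum to one and no infinite series is evaluated).  Both Poisson
#' tail orientations are available through `lower.tail`.
#'
#' @param w nonnegative evaluation points.
#' @param i,k record index and level (positive integers).
#' @param theta,lambda GED parameters.
#' @param lower.tail for `pkrecord`: if `TRUE` (default) return
#'   \eqn{P(W_{(i)} \le w)}; otherwise the survival probability.
#' @return Numeric vector.
#' @seealso [record_spec()], [extract_lower_krecords()]
#' @examples
#' dkrecord(0.3, i = 1, k = 2, theta = 1, lambda = 1) # density of max of 2
#' pkrecord(1, 2, 1, 1.5, 1) + skrecord(1, 2, 1, 1.5, 1)  # == 1
#' @export
dkrecord <- function(w, i, k, theta, lambda) {
  record_spec(i, k); ged_params(theta, lambda); .check_w(w)
  u <- theta * .tfun(w, lambda)          # -log G(w)
  pw <- if (i == 1) 0 else (i - 1) * log(u)   # avoid 0 * -Inf at u -> 0
  lg <- i * log(k) + pw - lgamma(i) - (k - 1) * u +
    dged(w, theta, lambda, log = TRUE)
  out <- exp(lg)
  ## limit at the origin is governed by t^{i-1} e^{-(k*theta-1)t}
  out[w == 0] <- if (k * theta > 1) 0
  else if (k * theta == 1 && i == 1) theta * lambda else Inf
  out
}

#' @rdname dkrecord
#' @export
pkrecord <- function(w, i, k, theta, lambda, lower.tail = TRUE) {
  record_spec(i, k); ged_params(theta, lambda); .check_w(w)
  stats::pgamma(k * theta * .tfun(w, lambda), shape = i, rate = 1,
                lower.tail = !lower.tail)
}

#' @rdname dkrecord
#' @export
skrecord <- function(w, i, k, theta, lambda) {
  pkrecord(w, i, k, theta, lambda, lower.tail = FALSE)
}

#' Quantile function of the i-th lower k-record value
#'
#' Inverts [pkrecord()] in closed form through the gamma quantile: the
#' p-quantile is \eqn{t^{-1}(q_{\Gamma(i)}(1-p)/(k\theta))}.  This is
#' also an exact one-step sampler for record values.
#'
#' @inheritParams dkrecord
#' @param p probabilities in (0, 1).
#' @export
qkrecord <- function(p, i, k, theta, lambda) {
  record_spec(i, k); ged_params(theta, lambda)
  if (any(p <= 0 | p >= 1)) stop("'p' must be in (0, 1)")
  u <- stats::qgamma(p, shape = i, rate = 1, lower.tail = FALSE)
  .tinv(u / (k * theta), lambda)
}

## Internal "base model" abstraction: a base is a list with elements
##   u(w)  = -log(base CDF at w)       (decreasing, positive)
##   logg(w) = log base density at w
## The record-value machinery (likelihood matrices, marginals) is
## written against this interface so the same code serves the GED base
## and the theta-marginalized base used for empirical-Bayes hyper-
## parameter estimation.
.base_ged <- function(theta, lambda) {
  list(
    u    = function(w) theta * .tfun(w, lambda),
    logg = function(w) dged(w, theta, lambda, log = TRUE)
  )
}

## Marginal base when theta ~ Exp(b) is integrated out observation-wise:
## CDF  G_b(w) = b / (b + t(w)),  pdf g_b = lambda e^{-lambda w + t} b/(b+t)^2.
.base_marginal <- function(b, lambda) {
  list(
    u    = function(w) log1p(.tfun(w, lambda) / b),
    logg = function(w) {
      t <- .tfun(w, lambda)
      log(lambda) - lambda * w + t + log(b) - 2 * log(b + t)
    }
  )
}

## record marginal cells for a generic base (vectorized over idx);
## log versions feed the log-space likelihood matrices
.rec_lcdf_base <- function(w, idx, k, base)
  stats::pgamma(k * base$u(w), shape = idx, rate = 1, lower.tail = FALSE,
                log.p = TRUE)
.rec_lsf_base <- function(w, idx, k, base)
  stats::pgamma(k * base$u(w), shape = idx, rate = 1, lower.tail = TRUE,
                log.p = TRUE)
.rec_lpdf_base <- function(w, idx, k, base) {
  u <- base$u(w)
  pw <- ifelse(idx == 1, 0, (idx - 1) * log(u))   # avoid 0 * -Inf
  idx * log(k) + pw - lgamma(idx) - (k - 1) * u + base$logg(w)
}
.rec_cdf_base <- function(w, idx, k, base) exp(.rec_lcdf_base(w, idx, k, base))
.rec_sf_base <- function(w, idx, k, base) exp(.rec_lsf_base(w, idx, k, base))
.rec_pdf_base <- function(w, idx, k, base) exp(.rec_lpdf_base(w, idx, k, base))
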