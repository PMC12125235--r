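## Pivotal prediction for future ordered OMELRRSS values.
##
## Working representation: if W is the i-th lower k-record of a
## GED(theta, lambda) stream, then U = k * theta * t(W), with
## t(w) = -log(1 - e^{-lambda w}), is exactly Gamma(i, 1).  Arranging
## the sample in DESCENDING order of W corresponds to ascending order of
## U, so the pivot
##     Psi = [t(z_tau) - t(z_s)] / t(z_s) = U_(tau) / U_(s) - 1
## is a ratio of order statistics of independent unit-rate gammas whose
## law depends only on the design (record indices, s, tau, n) -- free of
## theta, lambda and k.  Its survival function has an exact finite
## closed form because all gamma shapes are integers; a theta-dependent
## quadrature route through the GED-scale joint density and a
## stream-simulation Monte Carlo route are kept as independent checks.

#' Pivotal quantity for a future ordered value
#'
#' `[log(1 - e^{-lambda z_tau}) - log(1 - e^{-lambda z_s})] /
#' log(1 - e^{-lambda z_s})`, nonnegative in the descending convention
#' (the future value `z_tau` is smaller than the last observed `z_s`).
#' Multiplying both values by `c` and `lambda` by `1/c` leaves it
#' unchanged.
#'
#' @param z_tau future (smaller) value, `0 < z_tau < z_s`.
#' @param z_s last observed value.
#' @param lambda GED scale.
#' @return Nonnegative number.
#' @export
pivot_value <- function(z_tau, z_s, lambda) {
  if (any(z_tau <= 0) || any(z_s <= z_tau))
    stop("need 0 < z_tau < z_s (descending convention)")
  .tfun(z_tau, lambda) / .tfun(z_s, lambda) - 1
}

## ---- closed form -----------------------------------------------------------

## term table for one fixed design: rows (coef, a, alpha, b, beta, m)
## representing coef * (beta*c)^m / beta^(b+1) / (alpha + beta*c)^(a+m+1)
## with c = 1 + psi (factorials already folded into coef).
.pivot_terms <- function(idx, s, tau) {
  n <- length(idx)
  stopifnot(s >= 1, s < tau, tau <= n)
  mp <- .multiset_perms(idx)
  atoms <- function(kind, i) {
    m <- 0:(i - 1)
    switch(kind,
      F   = list(cf = c(1, -1 / factorial(m)), a = c(0L, m), al = c(0L, rep(1L, i)),
                 b = integer(i + 1), be = integer(i + 1)),
      fu  = list(cf = 1 / gamma(i), a = i - 1L, al = 1L, b = 0L, be = 0L),
      mid = list(cf = c(1 / factorial(m), -1 / factorial(m)),
                 a = c(m, integer(i)), al = c(rep(1L, i), integer(i)),
                 b = c(integer(i), m), be = c(integer(i), rep(1L, i))),
      fv  = list(cf = 1 / gamma(i), a = 0L, al = 0L, b = i - 1L, be = 1L),
      S   = list(cf = 1 / factorial(m), a = integer(i), al = integer(i),
                 b = m, be = rep(1L, i)))
  }
  kinds <- c(rep("F", s - 1), "fu", rep("mid", tau - s - 1), "fv",
             rep("S", n - tau))
  acc <- list(coef = numeric(0), a = integer(0), al = integer(0),
              b = integer(0), be = integer(0))
  for (pi in seq_len(nrow(mp$perms))) {
    p <- mp$perms[pi, ]
    cf <- 1; a <- 0L; al <- 0L; b <- 0L; be <- 0L
    for (q in seq_len(n)) {
      at <- atoms(kinds[q], p[q])
      nc <- length(cf); na <- length(at$cf)
      cf <- rep(cf, times = na) * rep(at$cf, each = nc)
      a  <- rep(a,  times = na) + rep(at$a,  each = nc)
      al <- rep(al, times = na) + rep(at$al, each = nc)
      b  <- rep(b,  times = na) + rep(at$b,  each = nc)
      be <- rep(be, times = na) + rep(at$be, each = nc)
    }
    acc$coef <- c(acc$coef, cf); acc$a <- c(acc$a, a); acc$al <- c(acc$al, al)
    acc$b <- c(acc$b, b); acc$be <- c(acc$be, be)
  }
  key <- paste(acc$a, acc$al, acc$b, acc$be)
  coef <- vapply(split(acc$coef, key), sum, numeric(1))
  uk <- do.call(rbind, strsplit(names(coef), " "))
  tt <- data.frame(coef = unname(coef), a = as.integer(uk[, 1]),
                   alpha = as.integer(uk[, 2]), b = as.integer(uk[, 3]),
                   beta = as.integer(uk[, 4]))
  tt <- tt[abs(tt$coef) > 0, , drop = FALSE]
  norm <- mp$mult / (gamma(s) * gamma(tau - s) * gamma(n - tau + 1))
  ## expand the inner incomplete-gamma sum over m = 0..b once
  ex <- tt[rep(seq_len(nrow(tt)), tt$b + 1L), , drop = FALSE]
  ex$m <- unlist(lapply(tt$b, function(bb) 0:bb))
  ex$coef <- ex$coef * norm *
    exp(lgamma(ex$b + 1) - lgamma(ex$m + 1) + lgamma(ex$a + ex$m + 1) -
          (ex$b + 1) * log(ex$beta))
  rownames(ex) <- NULL
  ex
}

.pivot_sf_closed_one <- function(psi, terms) {
  cc <- 1 + psi
  vapply(cc, function(c1)
    sum(terms$coef * (terms$beta * c1)^terms$m /
          (terms$alpha + terms$beta * c1)^(terms$a + terms$m + 1)),
    numeric(1))
}

#' Pivot specification
#'
#' Fixes the design against which the pivot distribution is evaluated:
#' last observed (descending) rank `s`, predicted rank `tau`, sampling
#' scheme and optional random sample-size model.  For a random size the
#' distribution mixes the per-size laws over `max(tau, rho):xi` with the
#' size pmf left-truncated at `tau`.  Closed-form term tables are
#' precomputed here.
#'
#' @param scheme a [scheme_config()] (used at its full size `n` for a
#'   fixed design, truncated per size for a random one).
#' @param s last observed descending rank.
#' @param tau predicted descending rank, `s < tau <= n`.
#' @param size_model `NULL` (fixed `n`) or a [size_model_uniform()].
#' @return An object of class `"pivot_spec"`.
#' @export
pivot_spec <- function(scheme, s, tau, size_model = NULL) {
  stopifnot(inherits(scheme, "scheme_config"))
  if (s < 1 || tau <= s) stop("need 1 <= s < tau")
  if (is.null(size_model)) {
    if (tau > scheme$n) stop("'tau' exceeds the sample size")
    sizes <- scheme$n; w <- 1
  } else {
    sizes <- .size_support(size_model, tau)
    w <- sample_size_pmf(sizes, size_model, truncate_at = tau)
  }
  designs <- lapply(sizes, function(n) {
    sch_n <- .truncate_scheme(scheme, n)
    list(n = n, idx = sch_n$record_indices,
         terms = .pivot_terms(sch_n$record_indices, s, tau))
  })
  structure(list(s = as.integer(s), tau = as.integer(tau), scheme = scheme,
                 size_model = size_model, sizes = sizes, weights = w,
                 designs = designs),
            class = "pivot_spec")
}

#' @export
print.pivot_spec <- function(x, ...) {
  cat(sprintf("pivot spec: s = %d, tau = %d, sizes {%s}\n", x$s, x$tau,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

## ---- quadrature route (theta-dependent scale) -----------------------------

#' Joint density of two descending ordered values
#'
#' Permanent-form joint density of `(z_s, z_tau)` (descending ranks
#' `s < tau`, so `x = z_s > y = z_tau`) for the INID record values of a
#' fixed-size design; zero when `y >= x`.
#'
#' @param x,y evaluation points (`x` for rank `s`, `y` for rank `tau`).
#' @param s,tau descending ranks.
#' @param scheme a [scheme_config()].
#' @param theta,lambda GED parameters.
#' @export
joint_density_two_os <- function(x, y, s, tau, scheme, theta, lambda) {
  stopifnot(inherits(scheme, "scheme_config"))
  ged_params(theta, lambda)
  n <- scheme$n; idx <- scheme$record_indices; k <- scheme$k
  if (s < 1 || tau <= s || tau > n) stop("need 1 <= s < tau <= n")
  base <- .base_ged(theta, lambda)
  one <- function(x1, y1) {
    if (y1 >= x1 || y1 <= 0) return(0)
    rows <- c(if (s > 1) rep(list(.rec_sf_base(x1, idx, k, base)), s - 1),
              list(.rec_pdf_base(x1, idx, k, base)),
              if (tau > s + 1) rep(list(.rec_cdf_base(x1, idx, k, base) -
                                          .rec_cdf_base(y1, idx, k, base)),
                                   tau - s - 1),
              list(.rec_pdf_base(y1, idx, k, base)),
              if (tau < n) rep(list(.rec_cdf_base(y1, idx, k, base)), n - tau))
    A <- do.call(rbind, rows)
    ## row scaling: the density rows diverge as y -> 0 when k*theta < 1,
    ## so the permanent is evaluated on row-normalized entries
    rmax <- apply(A, 1L, max)
    if (!all(is.finite(rmax))) return(0)
    if (any(rmax <= 0)) return(0)
    exp(sum(log(rmax)) + log(permanent(A / rmax)) -
          lgamma(s) - lgamma(tau - s) - lgamma(n - tau + 1))
  }
  mapply(one, x, y)
}

.pivot_sf_quad_one <- function(psi, s, tau, scheme, theta, lambda,
                               rel.tol = 1e-10) {
  ## integrate on the u = t(w) scale (x = tinv(ux), y = tinv(uy),
  ## region uy > (1+psi) ux), where the y -> 0 density singularity of
  ## small k*theta becomes exponential decay
  jac <- function(u) exp(-u) / (lambda * (-expm1(-u)))
  iq <- function(f, lo, hi, rtol) {
    tryCatch(stats::integrate(f, lo, hi, rel.tol = rtol, abs.tol = 1e-14,
                              subdivisions = 400L)$value,
             error = function(e)
               stats::integrate(f, lo, hi, rel.tol = rtol * 100,
                                abs.tol = 1e-12,
                                subdivisions = 400L)$value)
  }
  inner <- function(ux) {
    x <- .tinv(ux, lambda)
    iq(function(uy)
      joint_density_two_os(rep(x, length(uy)), .tinv(uy, lambda),
                           s, tau, scheme, theta, lambda) * jac(uy),
      (1 + psi) * ux, Inf, rel.tol)
  }
  iq(function(ux) vapply(ux, inner, numeric(1)) * jac(ux), 0, Inf,
     rel.tol * 10)
}

#' Survival function of the pivotal quantity
#'
#' `P(Psi > psi)` for the design in `spec`.  The default `closed_form`
#' method evaluates the exact finite-sum expression derived from the
#' unit-rate gamma representation of record values (all shapes are
#' integers, so no infinite series or special functions are involved);
#' `"quadrature"` integrates the permanent-form joint density of
#' `(z_s, z_tau)` on the original GED scale, which depends on `theta`
#' and `lambda` only through quadrature error -- the numerical
#' equality of the two routes at several `theta` is the scale- and
#' shape-freeness check of the test suite.
#'
#' @param psi nonnegative evaluation points.
#' @param spec a [pivot_spec()].
#' @param method evaluation route.
#' @param theta,lambda GED parameters used by the quadrature route.
#' @param rel.tol quadrature tolerance (quadrature route only).
#' @return Survival probabilities.
#' @export
pivot_sf <- function(psi, spec, method = c("closed_form", "quadrature"),
                     theta = 1, lambda = 1, rel.tol = 1e-10) {
  stopifnot(inherits(spec, "pivot_spec"))
  if (any(psi < 0)) stop("'psi' must be >= 0")
  method <- match.arg(method)
  if (method == "closed_form") {
    per_n <- vapply(spec$designs,
                    function(d) .pivot_sf_closed_one(psi, d$terms),
                    numeric(length(psi)))
    out <- if (length(psi) == 1L) sum(per_n * spec$weights)
           else as.numeric(matrix(per_n, nrow = length(psi)) %*% spec$weights)
  } else {
    out <- vapply(psi, function(ps) {
      v <- vapply(seq_along(spec$sizes), function(j) {
        sch_n <- .truncate_scheme(spec$scheme, spec$sizes[j])
        .pivot_sf_quad_one(ps, spec$s, spec$tau, sch_n, theta, lambda,
                           rel.tol = rel.tol)
      }, numeric(1))
      sum(v * spec$weights)
    }, numeric(1))
  }
  out
}

#' Pivot density
#'
#' Numerical derivative of one minus [pivot_sf()] (closed form).
#'
#' @inheritParams pivot_sf
#' @param h finite-difference step.
#' @export
pivot_pdf <- function(psi, spec, h = 1e-6) {
  (pivot_sf(pmax(psi - h, 0), spec) - pivot_sf(psi + h, spec)) /
    (psi + h - pmax(psi - h, 0))
}

#' Monte Carlo survival function of the pivot
#'
#' Simulates full OMELRRSS replicates (stream-based record process by
#' default), computes the pivot for each, and reports the exceedance
#' fraction with its binomial standard error.
#'
#' @inheritParams pivot_sf
#' @param reps number of replicates (`>= 1000`).
#' @param sampler passed to [generate_melrrss()] (`"stream"` or
#'   `"inverse"`).
#' @return A list with `sf` (vector along `psi`), `se` and `reps`.
#' @export
pivot_sf_mc <- function(psi, spec, theta = 1, lambda = 1, reps = 10000L,
                        sampler = c("stream", "inverse")) {
  stopifnot(inherits(spec, "pivot_spec"), reps >= 1000)
  sampler <- match.arg(sampler)
  ns <- if (length(spec$sizes) == 1L) rep(spec$sizes, reps)
        else sample(spec$sizes, reps, replace = TRUE, prob = spec$weights)
  schemes <- lapply(spec$sizes, .truncate_scheme, scheme = spec$scheme)
  names(schemes) <- spec$sizes
  psis <- vapply(ns, function(n) {
    z <- sort(generate_melrrss(schemes[[as.character(n)]], theta, lambda,
                               method = sampler), decreasing = TRUE)
    pivot_value(z[spec$tau], z[spec$s], lambda)
  }, numeric(1))
  sf <- vapply(psi, function(p) mean(psis > p), numeric(1))
  list(sf = sf, se = sqrt(sf * (1 - sf) / reps), reps = reps)
}

#' Pivot quantile
#'
#' Solves `P(Psi <= psi) = p` by bracketed root finding on the
#' closed-form (or quadrature) survival function.
#'
#' @param p probability level in (0, 1).
#' @inheritParams pivot_sf
#' @export
pivot_quantile <- function(p, spec, method = c("closed_form", "quadrature"),
                           theta = 1, lambda = 1) {
  if (p <= 0 || p >= 1) stop("'p' must be in (0, 1)")
  method <- match.arg(method)
  sf <- function(ps) pivot_sf(ps, spec, method, theta, lambda)
  hi <- 1
  while (sf(hi) > 1 - p) {
    hi <- hi * 2
    if (hi > 1e4) stop("no root found for the pivot quantile in [0, 1e4]")
  }
  stats::uniroot(function(ps) sf(ps) - (1 - p), c(0, hi), tol = 1e-10)$root
}

#' Pivotal prediction interval for a future ordered value
#'
#' For a descending censored sample observed through rank `s`, returns
#' the `(1 - pi)` predictive confidence interval for the unobserved
#' rank-`tau` value: upper limit `z_s`, lower limit
#' `-(1/lambda) log(1 - (1 - e^{-lambda z_s})^{psi + 1})` with `psi` the
#' `(1 - pi)` quantile of the pivot, so that
#' `P(l1 < z_tau <= z_s) = 1 - pi` exactly.
#'
#' @param sample a [censored_omelrrss()]; its descending view supplies
#'   `s` and `z_s`.
#' @param tau predicted descending rank (`> s`).
#' @param pi miscoverage level in (0, 1).
#' @param lambda GED scale.
#' @param size_model optional random sample-size model.
#' @param method SF evaluation route, see [pivot_sf()].
#' @return An object of class `"pci_result"`: `psi`, `lower`, `upper`,
#'   `width`, `level`, `method`.
#' @examples
#' fx <- omelrrss_fixture("renal_transplant", k = 1)
#' cs <- double_censor(fx$omelrrss, 2, 3, scheme = fx$scheme,
#'                     orientation = "descending")
#' solve_pci(cs, tau = 4, pi = 0.05, lambda = fx$lambda)
#' @export
solve_pci <- function(sample, tau, pi, lambda, size_model = NULL,
                      method = c("closed_form", "quadrature")) {
  stopifnot(inherits(sample, "censored_omelrrss"))
  if (pi <= 0 || pi >= 1) stop("'pi' must be in (0, 1)")
  method <- match.arg(method)
  ## descending view: z_s is the smallest observed value
  desc <- if (sample$orientation == "descending") sample else {
    n <- sample$scheme$n
    structure(list(window = rev(sample$window), r = n - sample$s + 1L,
                   s = n - sample$r + 1L, scheme = sample$scheme,
                   orientation = "descending",
                   values = if (!is.null(sample$values)) rev(sample$values)),
              class = "censored_omelrrss")
  }
  s <- desc$s
  z_s <- desc$window[length(desc$window)]
  spec <- pivot_spec(desc$scheme, s, tau, size_model)
  psi <- pivot_quantile(1 - pi, spec, method = method, lambda = lambda)
  lower <- .tinv((psi + 1) * .tfun(z_s, lambda), lambda)
  structure(list(psi = psi, lower = lower, upper = z_s,
                 width = z_s - lower, level = 1 - pi, method = method,
                 s = s, tau = as.integer(tau)),
            class = "pci_result")
}

#' @export
print.pci_result <- function(x, ...) {
  cat(sprintf("%.0f%% PCI for rank %d given rank %d: (%.6g, %.6g), width %.6g (psi = %.6g)\n",
              100 * x$level, x$tau, x$s, x$lower, x$upper, x$width, x$psi))
  invisible(x)
}
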