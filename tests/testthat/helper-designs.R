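# shared test utilities

# brute-force permanent by explicit permutation sum (oracle for Ryser)
bf_permanent <- function(A) {
  n <- nrow(A)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  sum(vapply(perms(seq_len(n)), function(p) prod(A[cbind(seq_len(n), p)]),
             numeric(1)))
}

# brute-force lower k-records by recomputing the k-th order statistic of
# every prefix (independent of the package's incremental scan)
bf_lower_krecords <- function(stream, k) {
  vals <- numeric(0)
  cur <- Inf
  for (j in k:length(stream)) {
    kth <- sort(stream[seq_len(j)])[k]
    if (kth < cur) { vals <- c(vals, kth); cur <- kth }
  }
  vals
}

# censored sample from explicit pieces
make_cs <- function(values, scheme, r, s, orientation = "ascending") {
  double_censor(omelrrss_sample(values, scheme, orientation), r, s)
}

# nested quadrature of the censored joint density over the ordered
# region, on the u = t(z) scale where the integrand decays exponentially
# (z_i = tinv(u_i), ascending z corresponds to descending u)
integrate_joint <- function(theta, lambda, scheme, r, s, rel.tol = 1e-8,
                            swap_censor = FALSE) {
  n <- scheme$n
  tinv <- function(u) -log1p(-exp(-u)) / lambda
  jac <- function(u) exp(-u) / (lambda * (-expm1(-u)))
  dens <- function(z) exp(omelrrss:::.loglik_fixed(
    theta, lambda, z, r, s, n, scheme$record_indices, scheme$k,
    swap_censor = swap_censor))
  m <- s - r + 1  # window length
  # recursively integrate u_m < u_{m-1} < ... < u_1 (z ascending)
  rec <- function(level, us) {
    upper <- if (level == 1L) Inf else us[level - 1L]
    f <- function(u) vapply(u, function(u1) {
      us[level] <- u1
      if (level == m) dens(tinv(us)) * prod(jac(us))
      else rec(level + 1L, us)
    }, numeric(1))
    stats::integrate(f, 0, upper, rel.tol = rel.tol, abs.tol = 1e-12,
                     subdivisions = 200L)$value
  }
  rec(1L, numeric(m))
}
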