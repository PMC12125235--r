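## Matrix permanents.  The joint density of order statistics of
## independent but non-identically distributed variables is a permanent
## of a matrix of marginal cdf/pdf/sf values, so a reliable permanent is
## the computational core of the censored-likelihood machinery.

#' Permanent of a square matrix
#'
#' Ryser's inclusion-exclusion formula,
#' \eqn{\mathrm{Per}(A) = (-1)^n \sum_{S \subseteq \{1..n\}} (-1)^{|S|}
#' \prod_i \sum_{j \in S} a_{ij}}, evaluated with Gray-code updates of
#' the running row sums (O(2^n n) flops).  Intended for the small
#' matrices of this package (`n <= 14`).
#'
#' @param A square numeric matrix.
#' @return The permanent, a single number.
#' @examples
#' permanent(matrix(c(1, 3, 2, 4), 2))  # 1*4 + 2*3 = 10
#' @export
permanent <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("'A' must be a square matrix")
  if (!all(is.finite(A))) stop("non-finite entries in 'A'")
  n <- nrow(A)
  if (n == 1L) return(A[1, 1])
  if (n == 2L) return(A[1, 1] * A[2, 2] + A[1, 2] * A[2, 1])
  if (n > 14L) stop("permanent supported for n <= 14 only")
  rs <- numeric(n)
  total <- 0
  prev <- 0L
  sz <- 0L
  for (m in seq_len(2^n - 1L)) {
    gray <- bitwXor(m, bitwShiftR(m, 1L))
    dbit <- bitwXor(gray, prev)            # single changed column
    j <- 1L + as.integer(round(log2(dbit)))
    if (bitwAnd(gray, dbit) > 0L) { rs <- rs + A[, j]; sz <- sz + 1L }
    else { rs <- rs - A[, j]; sz <- sz - 1L }
    prev <- gray
    total <- total + (-1)^sz * prod(rs)
  }
  (-1)^n * total
}

## Maximize a unimodal function on (lower, upper): coarse log-spaced
## scan to bracket the mode, then golden-section/Brent inside the
## bracket.  Plain optimize() is unreliable here because the objective
## underflows to -Inf over most of the interval.
.gridded_max <- function(f, lower, upper, tol = 1e-8, ngrid = 80L) {
  g <- exp(seq(log(lower), log(upper), length.out = ngrid))
  v <- f(g)
  j <- which.max(v)
  if (!is.finite(v[j])) stop("objective is -Inf over the whole search grid")
  lo <- g[max(j - 1L, 1L)]; hi <- g[min(j + 1L, ngrid)]
  opt <- stats::optimize(function(x) f(x), c(lo, hi), maximum = TRUE, tol = tol)
  if (opt$objective < v[j]) opt <- list(maximum = g[j], objective = v[j])
  opt
}

## Distinct permutations of a multiset (small n).  Returns a matrix with
## one arrangement per row, plus the common multiplicity with which each
## arrangement occurs among all n! column assignments.
.multiset_perms <- function(x) {
  n <- length(x)
  recurse <- function(items) {
    if (length(items) == 1L) return(matrix(items, 1L))
    vals <- unique(items)
    out <- lapply(vals, function(v) {
      rest <- items[-match(v, items)]
      cbind(v, recurse(rest), deparse.level = 0)
    })
    do.call(rbind, out)
  }
  perms <- recurse(x)
  mult <- prod(factorial(table(x)))
  list(perms = perms, mult = mult)
}
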