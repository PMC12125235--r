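## Design objects and samplers: lower k-record extraction from streams,
## MELRRSS / OMELRRSS generation, double type-II censoring, and the
## random-sample-size model.

#' MELRRSS design configuration
#'
#' Describes the moving-extremes lower k-record ranked set sampling
#' design: `m1` sequences contributing their 1st, 2nd, ..., m1-th lower
#' k-record and `m2` further sequences each contributing their first
#' (largest) lower k-record, for a total sample size `n = m1 + m2`.
#'
#' @param k record level (positive integer).
#' @param m1 number of sequences in the first phase.
#' @param m2 number of sequences in the second phase (`m2 <= m1`).
#' @param a nominal length of each underlying simple random sample
#'   stream (`a > n`); streams are extended in blocks of `a` when the
#'   required record has not yet occurred (an a.s. finite wait for
#'   continuous models).
#' @return An object of class `"scheme_config"` with fields `k`, `m1`,
#'   `m2`, `n`, `a` and `record_indices` (the per-slot record index
#'   multiset `c(1:m1, rep(1, m2))`).
#' @examples
#' scheme_config(k = 1, m1 = 5, m2 = 2)
#' @export
scheme_config <- function(k, m1, m2, a = 100L) {
  stopifnot(length(k) == 1L, length(m1) == 1L, length(m2) == 1L)
  if (k < 1 || k != round(k)) stop("'k' must be a positive integer")
  if (m1 < 1 || m1 != round(m1)) stop("'m1' must be a positive integer")
  if (m2 < 0 || m2 != round(m2)) stop("'m2' must be a nonnegative integer")
  if (m2 > m1) stop("'m2' must not exceed 'm1'")
  n <- m1 + m2
  if (a <= n) stop("'a' must exceed n = m1 + m2")
  structure(list(k = as.integer(k), m1 = as.integer(m1), m2 = as.integer(m2),
                 n = as.integer(n), a = as.integer(a),
                 record_indices = c(seq_len(m1), rep(1L, m2))),
            class = "scheme_config")
}

#' @export
print.scheme_config <- function(x, ...) {
  cat(sprintf("MELRRSS scheme: k = %d, m1 = %d, m2 = %d (n = %d), stream block a = %d\n",
              x$k, x$m1, x$m2, x$n, x$a))
  invisible(x)
}

## Truncate a scheme to its first n slots (used for random sample sizes):
## m1' = min(m1, n), m2' = n - m1'.
.truncate_scheme <- function(scheme, n) {
  m1 <- min(scheme$m1, n)
  scheme_config(scheme$k, m1, n - m1, a = scheme$a)
}

#' Extract lower k-record values from a data stream
#'
#' Classical lower k-records: the first record value is the k-th order
#' statistic (largest of the k smallest) of the first `k` observations;
#' a new record is emitted whenever the running k-th smallest strictly
#' decreases.  For `k = 1` this is the strictly-decreasing running
#' minimum.
#'
#' @param stream numeric vector, `length(stream) >= k`.
#' @param k record level.
#' @return An object of class `"record_trace"`: a list with `values`
#'   (strictly decreasing record values), `times` (positions of the
#'   observations that set each record; `times[1] = k`) and
#'   `inter_times` (`diff(times)`).
#' @examples
#' extract_lower_krecords(c(5, 3, 4, 2, 2, 1), k = 1)
#' @export
extract_lower_krecords <- function(stream, k) {
  if (!is.numeric(stream) || anyNA(stream)) stop("'stream' must be numeric without NA")
  if (k < 1 || k != round(k)) stop("'k' must be a positive integer")
  if (length(stream) < k) stop("stream shorter than k")
  k <- as.integer(k)
  if (k == 1L) {
    cm <- cummin(stream)
    new <- c(TRUE, cm[-1] < cm[-length(cm)])
    values <- cm[new]; times <- which(new)
  } else {
    bot <- sort(stream[seq_len(k)])       # k smallest seen so far, ascending
    values <- bot[k]; times <- k
    if (length(stream) > k) for (j in (k + 1L):length(stream)) {
      x <- stream[j]
      if (x < bot[k]) {                   # strict: ties do not set records
        bot <- sort(c(bot[-k], x))
        values <- c(values, bot[k]); times <- c(times, j)
      }
    }
  }
  structure(list(values = values, times = times,
                 inter_times = diff(times), k = k),
            class = "record_trace")
}

#' @rdname extract_lower_krecords
#' @details `extract_upper_krecords` is the sign-flip companion: it
#'   negates the stream, runs the lower-record machinery and negates
#'   the resulting values back.
#' @export
extract_upper_krecords <- function(stream, k) {
  tr <- extract_lower_krecords(-stream, k)
  tr$values <- -tr$values
  tr
}

#' @export
print.record_trace <- function(x, ...) {
  cat(sprintf("lower %d-record trace: %d record(s)\n", x$k, length(x$values)))
  print(data.frame(value = x$values, time = x$times))
  invisible(x)
}

## i-th lower k-record of a stream drawn via `draw(n)`, extending the
## stream in blocks until the record exists.  `draw` returns iid values.
.ith_record_stream <- function(i, k, draw, block, max_obs = 1e9) {
  ## memory-bounded chunked scan: inter-record waits are heavy-tailed
  ## (the expected wait for the second ordinary record is infinite), so
  ## chunks grow geometrically up to a cap and are discarded once
  ## scanned; only the running k smallest values are retained.
  first <- draw(k)
  bot <- sort(first)                     # k smallest seen so far
  nrec <- 1L
  seen <- k
  chunk <- max(block, 64L)
  while (nrec < i) {
    if (bot[k] == 0)
      stop("record value underflowed to zero; no smaller value is representable")
    if (seen > max_obs)
      stop("record did not occur within ", max_obs, " observations")
    x <- draw(chunk)
    seen <- seen + chunk
    if (k == 1L) {
      ## walk the strictly-decreasing running minimum inside the chunk
      j <- which(x < bot[1])
      while (length(j) && nrec < i) {
        bot[1] <- x[j[1]]
        nrec <- nrec + 1L
        j <- j[x[j] < bot[1]]
      }
    } else {
      for (xx in x) {
        if (xx < bot[k]) {
          bot <- sort(c(bot[-k], xx))
          nrec <- nrec + 1L
          if (nrec >= i) break
        }
      }
    }
    if (chunk < 4194304L) chunk <- 2L * chunk
  }
  bot[k]
}

#' Generate a MELRRSS sample
#'
#' Draws `m1 + m2` independent GED streams and records, per the design,
#' the l-th lower k-record from the l-th first-phase sequence and the
#' first lower k-record from each second-phase sequence.  The returned
#' vector is unordered (slot order as in `scheme$record_indices`).
#'
#' @param scheme a [scheme_config()].
#' @param theta,lambda GED parameters.
#' @param method `"stream"` runs the literal sequential record process
#'   on simulated streams; `"inverse"` draws each record value in one
#'   step through [qkrecord()] (exact, since the two laws coincide).
#' @return Numeric vector of length `n` with attribute `"indices"`.
#' @export
generate_melrrss <- function(scheme, theta, lambda,
                             method = c("stream", "inverse")) {
  stopifnot(inherits(scheme, "scheme_config"))
  ged_params(theta, lambda)
  method <- match.arg(method)
  idx <- scheme$record_indices
  if (method == "inverse") {
    u <- stats::rgamma(length(idx), shape = idx, rate = 1)
    out <- .tinv(u / (scheme$k * theta), lambda)
  } else {
    draw <- function(n) qged(stats::runif(n), theta, lambda)
    out <- vapply(idx, .ith_record_stream, numeric(1),
                  k = scheme$k, draw = draw, block = scheme$a)
  }
  attr(out, "indices") <- idx
  out
}

#' Order a MELRRSS sample
#'
#' @param x numeric vector (a MELRRSS sample).
#' @param orientation `"ascending"` (canonical storage) or
#'   `"descending"` (the view used by the prediction machinery).
#' @return Sorted numeric vector (stable for ties).
#' @export
order_to_omelrrss <- function(x, orientation = c("ascending", "descending")) {
  orientation <- match.arg(orientation)
  if (!length(x)) stop("empty sample")
  sort(x, decreasing = orientation == "descending", method = "radix")
}

#' Ordered sample container
#'
#' Wraps an ordered OMELRRSS vector together with its design metadata.
#'
#' @param values numeric vector of length `scheme$n` (sorted according
#'   to `orientation`; it is sorted here if not already).
#' @param scheme the generating [scheme_config()].
#' @param orientation sort direction of `values`.
#' @return An object of class `"omelrrss_sample"`.
#' @export
omelrrss_sample <- function(values, scheme,
                            orientation = c("ascending", "descending")) {
  stopifnot(inherits(scheme, "scheme_config"))
  orientation <- match.arg(orientation)
  if (length(values) != scheme$n) stop("length(values) must equal scheme$n")
  structure(list(values = order_to_omelrrss(values, orientation),
                 scheme = scheme, orientation = orientation),
            class = "omelrrss_sample")
}

#' Double type-II censoring of an ordered sample
#'
#' Retains ranks `r` through `s` of the ordered sample; the `r - 1`
#' values below rank `r` and the `n - s` values above rank `s` are
#' censored at `values[r]` and `values[s]` respectively (ranks counted
#' in the sample's own orientation).
#'
#' @param x an [omelrrss_sample()], or a raw ordered numeric vector
#'   together with `scheme`.
#' @param r,s censoring ranks, `1 <= r < s <= n`.
#' @param scheme required when `x` is a bare numeric vector.
#' @param orientation orientation of a bare numeric `x`.
#' @return An object of class `"censored_omelrrss"` with fields
#'   `window` (the observed slice), `r`, `s`, `scheme`, `orientation`
#'   and `values` (the full vector, when known).
#' @examples
#' sch <- scheme_config(1, 5, 2)
#' z <- omelrrss_sample(c(0.59, 0.12, 0.08, 0.05, 0.02, 0.01, 0.01), sch)
#' double_censor(z, 3, 5)$window
#' @export
double_censor <- function(x, r, s, scheme = NULL,
                          orientation = c("ascending", "descending")) {
  if (is.numeric(x)) {
    if (is.null(scheme)) stop("'scheme' is required for a bare numeric sample")
    x <- omelrrss_sample(x, scheme, match.arg(orientation))
  }
  stopifnot(inherits(x, "omelrrss_sample"))
  n <- x$scheme$n
  if (r < 1 || s <= r || s > n || r != round(r) || s != round(s))
    stop("need 1 <= r < s <= n")
  structure(list(window = x$values[r:s], r = as.integer(r), s = as.integer(s),
                 scheme = x$scheme, orientation = x$orientation,
                 values = x$values),
            class = "censored_omelrrss")
}

#' Construct a censored sample directly from an observed window
#'
#' For real data where only ranks `r..s` were measured.
#'
#' @param window the observed values at ranks `r..s` (monotone in the
#'   stated orientation).
#' @inheritParams double_censor
#' @export
censored_omelrrss <- function(window, r, s, scheme,
                              orientation = c("ascending", "descending")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(scheme, "scheme_config"))
  if (length(window) != s - r + 1) stop("window length must be s - r + 1")
  mono <- if (orientation == "ascending") !is.unsorted(window)
          else !is.unsorted(rev(window))
  if (!mono) stop("window not monotone in the stated orientation")
  structure(list(window = window, r = as.integer(r), s = as.integer(s),
                 scheme = scheme, orientation = orientation, values = NULL),
            class = "censored_omelrrss")
}

#' @export
print.censored_omelrrss <- function(x, ...) {
  cat(sprintf("double type-II censored OMELRRSS (%s), n = %d, r = %d, s = %d\n",
              x$orientation, x$scheme$n, x$r, x$s))
  cat("observed window:", paste(format(x$window), collapse = ", "), "\n")
  invisible(x)
}

## ascending view of a censored sample (the likelihood's canonical frame)
.as_ascending <- function(cs) {
  if (cs$orientation == "ascending") return(cs)
  n <- cs$scheme$n
  structure(list(window = rev(cs$window), r = n - cs$s + 1L, s = n - cs$r + 1L,
                 scheme = cs$scheme, orientation = "ascending",
                 values = if (!is.null(cs$values)) rev(cs$values) else NULL),
            class = "censored_omelrrss")
}

#' Sample size models
#'
#' `size_model_fixed(n)` is the degenerate model; in
#' `size_model_uniform(rho, xi)` the sample size `N` is discrete uniform
#' on `{rho, ..., xi}`.  When the analysis conditions on at least `s`
#' units having been observed, `N` is left-truncated at `s`, giving the
#' constant conditional pmf `1 / ((xi - rho + 1) P(N >= s))` on
#' `{max(s, rho), ..., xi}`.
#'
#' @param n fixed sample size.
#' @param rho,xi support endpoints, `rho <= xi`.
#' @return An object of class `"size_model"`.
#' @export
size_model_fixed <- function(n) {
  if (n < 1 || n != round(n)) stop("'n' must be a positive integer")
  structure(list(kind = "fixed", n = as.integer(n)), class = "size_model")
}

#' @rdname size_model_fixed
#' @export
size_model_uniform <- function(rho, xi) {
  if (rho < 1 || rho != round(rho) || xi != round(xi) || xi < rho)
    stop("need integers 1 <= rho <= xi")
  structure(list(kind = "discrete_uniform", rho = as.integer(rho),
                 xi = as.integer(xi)), class = "size_model")
}

#' Probability mass of the sample-size model
#'
#' @param n integer values at which to evaluate the pmf.
#' @param model a [size_model_fixed()] or [size_model_uniform()].
#' @param truncate_at if non-`NULL`, return the left-truncated pmf
#'   `P(N = n | N >= truncate_at)` (zero outside the truncated support;
#'   requires `truncate_at <= xi` for the uniform model).
#' @return Numeric vector of probabilities.
#' @examples
#' m <- size_model_uniform(2, 7)
#' sample_size_pmf(4:7, m, truncate_at = 4)  # each 1/4
#' @export
sample_size_pmf <- function(n, model, truncate_at = NULL) {
  stopifnot(inherits(model, "size_model"))
  if (model$kind == "fixed") {
    p <- as.numeric(n == model$n)
    if (!is.null(truncate_at) && truncate_at > model$n)
      stop("truncation point exceeds the fixed size")
    return(p)
  }
  rho <- model$rho; xi <- model$xi
  if (is.null(truncate_at)) return(ifelse(n >= rho & n <= xi, 1 / (xi - rho + 1), 0))
  s <- truncate_at
  if (s > xi) stop("truncation point exceeds 'xi'")
  p_ge_s <- if (s <= rho) 1 else 1 - (s - rho) / (xi - rho + 1)
  ifelse(n >= max(s, rho) & n <= xi, 1 / ((xi - rho + 1) * p_ge_s), 0)
}

## support of the (possibly truncated) size model
.size_support <- function(model, truncate_at = 1L) {
  if (model$kind == "fixed") {
    if (truncate_at > model$n) stop("truncation point exceeds the fixed size")
    return(model$n)
  }
  max(truncate_at, model$rho):model$xi
}

#' Draw a sample size
#'
#' @inheritParams sample_size_pmf
#' @return A single integer.
#' @export
draw_sample_size <- function(model, truncate_at = NULL) {
  stopifnot(inherits(model, "size_model"))
  if (model$kind == "fixed") return(model$n)
  supp <- .size_support(model, if (is.null(truncate_at)) 1L else truncate_at)
  if (length(supp) == 1L) supp else supp[sample.int(length(supp), 1L)]
}

#' Read a raw data stream from a text file
#'
#' Accepts whitespace-separated or CSV text with one value per record;
#' non-numeric header lines are skipped.
#'
#' @param path file path.
#' @return Numeric vector.
#' @export
read_stream <- function(path) {
  raw <- scan(path, what = character(), sep = if (grepl("\\.csv$", path)) "," else "",
              quiet = TRUE)
  x <- suppressWarnings(as.numeric(raw))
  x[!is.na(x)]
}

#' Write a record trace to CSV
#'
#' Columns: `sequence`, `record_index`, `value`, `time`.
#'
#' @param trace a `record_trace` or a list of them.
#' @param path output file path.
#' @export
write_record_trace <- function(trace, path) {
  if (inherits(trace, "record_trace")) trace <- list(trace)
  df <- do.call(rbind, lapply(seq_along(trace), function(j) {
    tr <- trace[[j]]
    data.frame(sequence = j, record_index = seq_along(tr$values),
               value = tr$values, time = tr$times)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
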