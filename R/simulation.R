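## Monte Carlo harnesses: estimator comparison (AV / ABE / RAB) and
## prediction-interval evaluation (PC / IW / AIW).
##
## The two study drivers reconstruct the usual design loop: draw the
## (possibly random) sample size, generate a MELRRSS replicate, order
## it, apply double type-II censoring, and either estimate the shape
## parameter with every requested estimator or build the pivotal
## prediction interval and score containment of the held-out rank.
## Metrics: AV = mean estimate, ABE = mean absolute error,
## RAB = ABE / true theta; PC = containment proportion, AIW = mean
## interval width.

#' Configuration for an estimation study
#'
#' @param true_theta,lambda generating GED parameters.
#' @param prior_b exponential prior rate used by the Bayes estimators.
#' @param scheme a [scheme_config()].
#' @param r,s censoring ranks.
#' @param size_model `NULL` for fixed `n`, or a [size_model_uniform()]
#'   (the per-replicate size is drawn from its left-truncation at `s`).
#' @param estimators subset of `"mle"`, `"se"`, `"linex"`, `"bse"`,
#'   `"blinex"`, `"eb_bse"`, `"eb_blinex"`.
#' @param c_linex LINEX asymmetry value(s).
#' @param delta balanced-loss weight.
#' @param reps number of replicates.
#' @param sampler record-value sampler passed to [generate_melrrss()].
#' @param bayes_method posterior evaluation route for the Bayes
#'   estimators (the closed form is exact and fast for the small designs
#'   used in simulation; equivalence of the two routes is a test-suite
#'   invariant).
#' @return A list of class `"est_sim_config"`.
#' @export
est_sim_config <- function(true_theta, lambda, prior_b, scheme, r, s,
                           size_model = NULL,
                           estimators = c("mle", "se", "bse"),
                           c_linex = 0.1, delta = 0.5, reps = 500L,
                           sampler = "stream",
                           bayes_method = "closed_form") {
  ged_params(true_theta, lambda)
  stopifnot(inherits(scheme, "scheme_config"), reps >= 1)
  known <- c("mle", "se", "linex", "bse", "blinex", "eb_bse", "eb_blinex")
  if (!all(estimators %in% known)) stop("unknown estimator name")
  structure(list(true_theta = true_theta, lambda = lambda, prior_b = prior_b,
                 scheme = scheme, r = as.integer(r), s = as.integer(s),
                 size_model = size_model, estimators = estimators,
                 c_linex = c_linex, delta = delta, reps = as.integer(reps),
                 sampler = sampler, bayes_method = bayes_method),
            class = "est_sim_config")
}

## one replicate's censored sample (random size drawn if needed)
.sim_censored <- function(scheme, r, s, theta, lambda, size_model, sampler) {
  n <- if (is.null(size_model)) scheme$n else draw_sample_size(size_model, s)
  sch_n <- .truncate_scheme(scheme, n)
  z <- generate_melrrss(sch_n, theta, lambda, method = sampler)
  double_censor(omelrrss_sample(z, sch_n), r, s)
}

#' Run an estimation study
#'
#' Generates `reps` independent censored OMELRRSS replicates at the
#' fixed true shape and computes every requested estimator on each;
#' per-replicate failures are counted, not fatal.
#'
#' @param cfg an [est_sim_config()].
#' @param .estimate_fn optional replacement estimator
#'   `function(sample, cfg) named numeric vector` (used for harness
#'   self-tests).
#' @return A list of class `"est_sim_report"`: `summary` (data frame
#'   with AV, ABE, RAB per estimator), `estimates` (replicate-level
#'   matrix, one row per replicate), `failures`.
#' @export
run_estimation_study <- function(cfg, .estimate_fn = NULL) {
  stopifnot(inherits(cfg, "est_sim_config"))
  est_one <- if (!is.null(.estimate_fn)) .estimate_fn else function(cs, cfg) {
    out <- c()
    size_model <- cfg$size_model
    prior <- prior_spec(cfg$prior_b)
    need_mle <- any(c("mle", "bse", "blinex", "eb_bse", "eb_blinex") %in%
                      cfg$estimators)
    ml <- if (need_mle) mle_theta(cs, cfg$lambda, size_model)$theta
    if ("mle" %in% cfg$estimators) out["mle"] <- ml
    m <- cfg$bayes_method
    if (any(c("se", "linex", "bse", "blinex") %in% cfg$estimators)) {
      ps <- posterior_summary(cs, cfg$lambda, prior, c = cfg$c_linex,
                              size_model = size_model, method = m)
      if ("se" %in% cfg$estimators) out["se"] <- ps$mean
      if ("linex" %in% cfg$estimators)
        out[paste0("linex_c", cfg$c_linex)] <- -log(ps$linex) / cfg$c_linex
      if ("bse" %in% cfg$estimators)
        out["bse"] <- cfg$delta * ml + (1 - cfg$delta) * ps$mean
      if ("blinex" %in% cfg$estimators)
        out[paste0("blinex_c", cfg$c_linex)] <-
          -log(cfg$delta * exp(-cfg$c_linex * ml) +
                 (1 - cfg$delta) * ps$linex) / cfg$c_linex
    }
    if (any(c("eb_bse", "eb_blinex") %in% cfg$estimators)) {
      bt <- estimate_hyperparameter_b(cs, cfg$lambda, size_model)$b
      ps <- posterior_summary(cs, cfg$lambda, prior_spec(bt), c = cfg$c_linex,
                              size_model = size_model, method = m)
      if ("eb_bse" %in% cfg$estimators)
        out["eb_bse"] <- cfg$delta * ml + (1 - cfg$delta) * ps$mean
      if ("eb_blinex" %in% cfg$estimators)
        out[paste0("eb_blinex_c", cfg$c_linex)] <-
          -log(cfg$delta * exp(-cfg$c_linex * ml) +
                 (1 - cfg$delta) * ps$linex) / cfg$c_linex
    }
    out
  }
  rows <- vector("list", cfg$reps)
  failures <- 0L
  for (rep in seq_len(cfg$reps)) {
    cs <- .sim_censored(cfg$scheme, cfg$r, cfg$s, cfg$true_theta, cfg$lambda,
                        cfg$size_model, cfg$sampler)
    rows[[rep]] <- tryCatch(est_one(cs, cfg), error = function(e) {
      failures <<- failures + 1L
      NULL
    })
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  est <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(colnames(est), function(nm) {
    s <- summarize_estimates(est[, nm], cfg$true_theta)
    data.frame(estimator = nm, AV = s["AV"], ABE = s["ABE"], RAB = s["RAB"],
               row.names = NULL)
  }))
  structure(list(summary = summ, estimates = est, failures = failures,
                 config = cfg),
            class = "est_sim_report")
}

#' @export
print.est_sim_report <- function(x, ...) {
  cat(sprintf("estimation study: %d replicate(s), %d failure(s), true theta = %g\n",
              nrow(x$estimates), x$failures, x$config$true_theta))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Configuration for a prediction study
#'
#' @inheritParams est_sim_config
#' @param s last observed descending rank.
#' @param tau predicted descending rank.
#' @param pi miscoverage level(s).
#' @export
pred_sim_config <- function(true_theta, lambda, scheme, s, tau, pi = 0.05,
                            size_model = NULL, reps = 2000L,
                            sampler = "stream") {
  ged_params(true_theta, lambda)
  stopifnot(inherits(scheme, "scheme_config"), s >= 1, tau > s, reps >= 1)
  structure(list(true_theta = true_theta, lambda = lambda, scheme = scheme,
                 s = as.integer(s), tau = as.integer(tau), pi = pi,
                 size_model = size_model, reps = as.integer(reps),
                 sampler = sampler),
            class = "pred_sim_config")
}

#' Run a prediction study
#'
#' Per replicate: draw the (possibly random) size, generate and order a
#' full sample descending, hide ranks beyond `s`, build the pivotal PCI
#' for rank `tau`, and record containment of the true hidden value and
#' the interval width.  The pivot quantile depends only on the design so
#' it is solved once per level.
#'
#' @param cfg a [pred_sim_config()].
#' @return A list of class `"pred_sim_report"`: `summary` (PC and AIW
#'   per level), `detail` (per-replicate hits and widths).
#' @export
run_prediction_study <- function(cfg) {
  stopifnot(inherits(cfg, "pred_sim_config"))
  spec <- pivot_spec(cfg$scheme, cfg$s, cfg$tau, cfg$size_model)
  psis <- vapply(cfg$pi, function(p) pivot_quantile(1 - p, spec), numeric(1))
  hits <- matrix(NA, cfg$reps, length(cfg$pi))
  widths <- matrix(NA_real_, cfg$reps, length(cfg$pi))
  for (rep in seq_len(cfg$reps)) {
    n <- if (is.null(cfg$size_model)) cfg$scheme$n
         else draw_sample_size(cfg$size_model, cfg$tau)
    sch_n <- .truncate_scheme(cfg$scheme, n)
    z <- sort(generate_melrrss(sch_n, cfg$true_theta, cfg$lambda,
                               method = cfg$sampler), decreasing = TRUE)
    z_s <- z[cfg$s]; z_tau <- z[cfg$tau]
    lower <- .tinv((psis + 1) * .tfun(z_s, cfg$lambda), cfg$lambda)
    hits[rep, ] <- z_tau > lower           # upper limit z_s always holds
    widths[rep, ] <- z_s - lower
  }
  summ <- do.call(rbind, lapply(seq_along(cfg$pi), function(j) {
    s <- summarize_intervals(hits[, j], widths[, j])
    data.frame(pi = cfg$pi[j], psi = psis[j], PC = s["PC"], AIW = s["AIW"],
               row.names = NULL)
  }))
  structure(list(summary = summ, detail = list(hits = hits, widths = widths),
                 config = cfg),
            class = "pred_sim_report")
}

#' @export
print.pred_sim_report <- function(x, ...) {
  cat(sprintf("prediction study: %d replicate(s), s = %d, tau = %d\n",
              x$config$reps, x$config$s, x$config$tau))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Aggregate estimation metrics
#'
#' AV = mean estimate, ABE = mean absolute error, RAB = ABE / theta.
#'
#' @param estimates numeric vector of estimates.
#' @param true_theta true shape value.
#' @return Named vector `c(AV, ABE, RAB)`.
#' @export
summarize_estimates <- function(estimates, true_theta) {
  if (!length(estimates)) stop("empty estimate vector")
  abe <- mean(abs(estimates - true_theta))
  c(AV = mean(estimates), ABE = abe, RAB = abe / true_theta)
}

#' Aggregate prediction-interval metrics
#'
#' PC = containment proportion, AIW = mean width.
#'
#' @param hits logical vector of containment indicators.
#' @param widths numeric vector of interval widths.
#' @return Named vector `c(PC, AIW)`.
#' @export
summarize_intervals <- function(hits, widths) {
  if (!length(hits) || length(hits) != length(widths))
    stop("'hits' and 'widths' must be nonempty and of equal length")
  c(PC = mean(hits), AIW = mean(widths))
}
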