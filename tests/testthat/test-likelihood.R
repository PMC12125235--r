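test_that("Ryser permanent matches the brute-force permutation sum", {
  expect_equal(permanent(matrix(c(1, 3, 2, 4), 2)), 10)
  expect_equal(permanent(diag(6)), 1)
  set.seed(41)
  A <- matrix(runif(25), 5)
  expect_equal(permanent(A), bf_permanent(A), tolerance = 1e-12)
  # duplicated columns (the m2 first-record columns of the design)
  A[, 4] <- A[, 2]
  expect_equal(permanent(A), bf_permanent(A), tolerance = 1e-12)
  expect_error(permanent(matrix(1:6, 2)))
})

test_that("distributional matrix has the documented block structure", {
  fx <- omelrrss_fixture("nerve_impulse", 1)
  cs <- double_censor(fx$melrrss, 3, 5, scheme = fx$scheme)
  A <- build_dist_matrix(0.9, cs, fx$lambda)
  expect_equal(dim(A), c(7, 7))
  expect_equal(attr(A, "row_kind"),
               c("cdf", "cdf", "pdf", "pdf", "pdf", "sf", "sf"))
  # censor rows are probabilities
  expect_true(all(A[c(1, 2, 6, 7), ] >= 0 & A[c(1, 2, 6, 7), ] <= 1))
  expect_equal(A[1, ], A[2, ])
  # uncensored design: only density rows
  full <- double_censor(fx$melrrss, 1, 7, scheme = fx$scheme)
  expect_equal(attr(build_dist_matrix(0.9, full, fx$lambda), "row_kind"),
               rep("pdf", 7))
})

test_that("censored joint density integrates to one (and fixes the censor orientation)", {
  # n = 2 uncensored designs
  for (cfg in list(c(2, 0), c(1, 1))) {
    sch <- scheme_config(2, cfg[1], cfg[2], a = 50)
    expect_equal(integrate_joint(1.6, 1.2, sch, r = 1, s = 2), 1,
                 tolerance = 1e-6)
  }
  # censored n = 2 and n = 3 designs
  sch3 <- scheme_config(1, 2, 1, a = 50)
  expect_equal(integrate_joint(0.8, 1.5, sch3, r = 2, s = 3), 1,
               tolerance = 1e-5)
  expect_equal(integrate_joint(1.2, 1, sch3, r = 1, s = 2), 1,
               tolerance = 1e-5)
  # the swapped censor orientation does NOT normalize: it integrates to
  # 2 for the n = 3, r = 2, s = 3 design, which is what pins the
  # convention used by build_dist_matrix
  expect_equal(integrate_joint(0.8, 1.5, sch3, r = 2, s = 3,
                               swap_censor = TRUE), 2, tolerance = 1e-4)
})

test_that("series expansion agrees with the permanent form", {
  set.seed(42)
  for (rep in 1:10) {
    m1 <- sample(2:3, 1); m2 <- sample(0:min(2, m1), 1)
    n <- m1 + m2
    if (n < 3) next
    sch <- scheme_config(sample(c(1, 2, 3), 1), m1, m2, a = 50)
    pick1 <- function(v) v[sample.int(length(v), 1)]
    r <- pick1(1:(n - 1)); s <- pick1((r + 1):n)
    theta <- runif(1, 0.4, 2.5); lambda <- runif(1, 0.5, 2)
    z <- sort(generate_melrrss(sch, theta, lambda, method = "inverse"))
    cs <- double_censor(z, r, s, scheme = sch)
    lp <- likelihood_permanent(theta, cs, lambda)
    ls <- likelihood_series(theta, cs, lambda)                       # truncated sums
    lc <- likelihood_series(theta, cs, lambda, sf_form = "complement")  # exact
    expect_equal(ls / lp, 1, tolerance = 1e-6)
    expect_equal(lc / lp, 1, tolerance = 1e-9)
  }
  # degenerate uniform size model reproduces the fixed-size value
  sch <- scheme_config(1, 3, 1, a = 50)
  z <- sort(generate_melrrss(sch, 1, 1, method = "inverse"))
  cs <- double_censor(z, 2, 3, scheme = sch)
  expect_equal(likelihood_series(1.3, cs, 1, size_model = size_model_uniform(4, 4)),
               likelihood_series(1.3, cs, 1), tolerance = 1e-12)
  expect_error(likelihood_terms(cs, 1, trunc = truncation_policy(lmax = 7)))
})

test_that("MLE solves the score equation and is scale equivariant", {
  fx <- omelrrss_fixture("nerve_impulse", 1)
  cs <- double_censor(fx$omelrrss, fx$r, fx$s, scheme = fx$scheme,
                      orientation = "descending")
  m <- mle_theta(cs, fx$lambda)
  expect_true(m$converged)
  expect_lt(abs(m$score), 1e-3)
  # the estimate maximizes the log-likelihood locally
  ll <- function(th) loglik_theta(th, cs, fx$lambda)
  expect_gt(m$loglik, ll(m$theta * 1.05))
  expect_gt(m$loglik, ll(m$theta * 0.95))
  # ascending and descending views give the same likelihood and MLE
  cs_a <- double_censor(fx$melrrss, fx$r, fx$s, scheme = fx$scheme)
  expect_equal(mle_theta(cs_a, fx$lambda)$theta, m$theta, tolerance = 1e-6)
  # scale equivariance: data * c with lambda / c leaves theta-hat fixed
  for (cc in c(0.25, 4)) {
    cs2 <- double_censor(fx$omelrrss * cc, fx$r, fx$s, scheme = fx$scheme,
                         orientation = "descending")
    expect_equal(mle_theta(cs2, fx$lambda / cc)$theta, m$theta,
                 tolerance = 1e-4)
  }
})

test_that("MLE recovers the true shape on complete simulated samples", {
  sch <- scheme_config(1, 5, 2, a = 100)
  set.seed(43)
  est <- replicate(200, {
    z <- generate_melrrss(sch, 2, 1, method = "inverse")
    mle_theta(double_censor(z, 1, 7, scheme = sch), 1)$theta
  })
  expect_lt(abs(mean(est) - 2) / 2, 0.15)
})

test_that("random sample size mixes the per-size likelihoods", {
  sch <- scheme_config(1, 3, 2, a = 50)
  z <- c(0.2, 0.5, 0.9, 1.4, 2.2)
  cs <- double_censor(z, 2, 4, scheme = sch)
  sm <- size_model_uniform(2, 5)
  # manual mixture over n = 4, 5 with the s-truncated weights
  w <- sample_size_pmf(4:5, sm, truncate_at = 4)
  l4 <- exp(omelrrss:::.loglik_fixed(1.1, 1, z[2:4], 2, 4, 4,
                                     c(1, 2, 3, 1), 1))
  l5 <- likelihood_permanent(1.1, cs, 1)
  expect_equal(exp(loglik_theta(1.1, cs, 1, size_model = sm)),
               w[1] * l4 + w[2] * l5, tolerance = 1e-10)
  # and the series route agrees
  expect_equal(likelihood_series(1.1, cs, 1, size_model = sm),
               w[1] * l4 + w[2] * l5, tolerance = 1e-6)
  m <- mle_theta(cs, 1, size_model = sm)
  expect_true(m$converged)
})
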