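---
title: "Methods: record-based ranked set sampling inference for GED lifetimes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: record-based ranked set sampling inference for GED lifetimes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omelrrss)
```

## The sampling design and the model

In reliability and survival studies where measuring a unit is expensive
but ranking units is cheap, ranked set sampling buys precision per
measurement.  The design implemented here pushes that idea to record
values: `m1` independent observation streams are run, the `l`-th stream
stopping when its `l`-th **lower k-record** appears (the running k-th
smallest value, each time it strictly decreases), and `m2` further
streams each contribute their first (largest) lower k-record.  The
`n = m1 + m2` measured values are *independent but not identically
distributed* (INID): slot `l` carries the marginal law of an `l`-th
lower k-record.  Sorting them gives the ordered sample
`z(1) <= ... <= z(n)`, and double type-II censoring observes only ranks
`r` through `s`.

Lifetimes are modelled by the generalized exponential distribution
(GED) with CDF `G(w) = (1 - exp(-lambda w))^theta`, shape `theta > 0`
and rate `lambda > 0` (per unit time).  Its hazard decreases for
`theta < 1`, is constant `lambda` at `theta = 1`, and increases for
`theta > 1`, which is what makes it a workable flexible lifetime family
here; inference targets `theta` with `lambda` treated as known
throughout (the usual assumption for this design, and the one under
which the pivotal prediction below is exact).

### The gamma representation

Everything in this package rests on one identity.  Writing
`t(w) = -log(1 - exp(-lambda w))`, the `i`-th lower k-record `W` of a
GED stream satisfies

    k * theta * t(W)  ~  Gamma(shape = i, rate = 1)        (exactly).

Consequences used throughout:

* the record marginal CDF is the *upper* gamma tail
  `P(Gamma(i, 1) > k * theta * t(w))`, a finite Poisson-type sum --
  no infinite series is ever required for the record CDF/SF pair,
  which always sums to one by construction (`pkrecord` / `skrecord`);
* `qkrecord` inverts it in closed form, giving an exact one-step
  sampler for record values (`generate_melrrss(..., method =
  "inverse")`), validated against the literal sequential record
  process (`method = "stream"`) by distributional tests;
* the prediction pivot below is distribution-free.

A note on conventions: for *lower* records the finite Poisson sum
`G^k * sum_{v < i} (-k log G)^v / v!` is the CDF (it increases from 0
to 1 in `w`; at `i = 1` it is `G^k`, the CDF of the maximum of `k`
draws), and the matching infinite series is the survival function.
Because labels for these two quantities are easy to transpose in this
literature, the package exposes both tail orientations explicitly and
pins the one used in the likelihood by a normalization test: for the
`n = 3`, `r = 2`, `s = 3` censored design the correctly oriented joint
density integrates to 1 while the swapped orientation integrates to 2
(the `n = 2` designs do not discriminate -- both orientations normalize
by symmetry -- which is why the discriminating test is part of the
suite).

## The censored likelihood

For INID order statistics the joint density of the observed window is a
matrix **permanent**:

    L(theta) = Per(A) / ((r-1)! (n-s)!),

where `A` has `r - 1` identical rows of record-marginal CDFs at `z_r`,
one density row per observed rank, and `n - s` identical rows of
survival values at `z_s`; column `j` carries record index
`record_indices[j]` at level `k`.  `permanent()` implements Ryser's
inclusion-exclusion with Gray-code updates (O(2^n n)), ample for the
small `n` of this design; matrices are assembled in log scale and
row-scaled so that extreme record values (whose densities can exceed
double range) remain usable.

The same density expands into a finite mixture of gamma kernels.  Each
matrix cell is a polynomial in `theta` times `exp(-k theta t)`, so each
permutation's product contributes terms `coef * theta^eta *
exp(-theta W)`.  `likelihood_terms()` builds this table by iterating
distinct multiset permutations of the record indices (duplicate
first-record columns collapsed, which is exact and far cheaper than all
`n!`).  Two right-censor expansions are provided: the *complement* form
(`1 - CDF`, finite and exact -- the default backbone of the closed-form
posterior quantities) and the *series* form (truncated infinite
Poisson-tail sums, cap `lmax = 60` by default; the discarded tail is a
Poisson tail beyond `lmax`, negligible whenever
`k * theta * t(z_s) + 5 sqrt(k * theta * t(z_s)) < lmax`).  Series and
permanent evaluations agree to better than 1e-6 relative error across
randomized designs in the test suite -- they are algebraically the same
object computed by different routes.

**Random sample sizes.**  When the number of available sequences is
itself random, `N ~ Uniform(rho, xi)` left-truncated at `s` (constant
conditional pmf `1/((xi - rho + 1) P(N >= s))` on `max(s, rho):xi`),
the likelihood mixes the per-size densities over that finite support.
The design for size `n` is taken to be the scheme truncated to its
first `n` sequences (`m1' = min(m1, n)`, `m2' = n - m1'`); this split
is a modelling choice -- the design literature does not fix it -- and
is surfaced in the fitted objects so it can be audited.

**Maximum likelihood.**  `mle_theta()` runs Newton-Raphson on the score
(numerical derivatives, step `1e-5 * max(1, theta)`), stopping when
successive iterates move less than `tol = 1e-6` with a 100-iteration
cap, and falls back to golden-section search when the iteration leaves
the parameter space or meets a non-concave stretch.  Because the
log-likelihood underflows to `-Inf` far from its mode, all fallback and
mode searches first bracket the maximum on a coarse log-spaced grid.
The default start is a method-of-moments value under the `theta = 1`
submodel, `mean(i) / (k * mean(t(window)))` -- cheap and always inside
the domain.  The MLE is scale equivariant (multiplying the data by `c`
and `lambda` by `1/c` leaves it fixed), which the suite checks.

## Bayes, balanced losses, empirical Bayes

`theta` gets an exponential prior with rate `b` (mean `1/b`).  The
posterior is likelihood times prior; two evaluation routes are kept
deliberately independent:

* **quadrature** (the default): adaptive integration against the
  permanent-form posterior, with the integrand shifted by its log-mode
  for stability;
* **closed form**: the term table integrates against the prior in
  gamma integrals, `sum coef * Gamma(eta + 1) / (b + W)^(eta + 1)` and
  relatives -- exact, fast, and the cross-check route (agreement to
  1e-5 relative error is an acceptance-grade test; the simulation
  harness uses this route for speed at its small designs).

Point estimators: squared-error loss gives the posterior mean; LINEX
loss with asymmetry `c` gives `-(1/c) log E[exp(-c theta) | z]`
(continuous in `c` with the SE limit at `c -> 0`, and decreasing in
`c`).  The *balanced* versions mix in a target estimator -- here the
MLE -- with weight `delta`: BSE is the convex combination
`delta * mle + (1 - delta) * posterior mean`, BLINEX the log-convex
analogue on the `exp(-c theta)` scale; `delta` endpoints reproduce the
components exactly.

**Empirical Bayes.**  When `b` is unknown it is estimated by maximum
likelihood under the *marginal* base model obtained by integrating
`theta` out of the GED observation-wise: the marginal base CDF is
`b / (b + t(w))` and density `lambda e^{-lambda w} e^{t} b / (b + t)^2`.
That pair is pushed through the same record/censoring likelihood
machinery and maximized over `b` by bounded search on `(1e-6, 1e3)`
(boundary maxima flagged).  Two caveats worth knowing: the
marginalization is done at the base-observation level *before* the
record construction (the alternative -- one shared `theta` for the whole
experiment -- would instead make the prior-predictive normalizing
constant the marginal likelihood); and the marginal base is extremely
heavy-tailed toward zero (`t` at its deep records grows like
`b(e^u - 1)` with `u ~ Gamma(i, 1)`), so record values from it with
index 5 underflow double precision in a sizeable fraction of
replicates.  The recovery test therefore exercises a design with
record indices up to 3, where underflow is rare and the estimator's
median lands near the truth.

## Pivotal prediction

For prediction the sample is viewed in *descending* order (largest
first); ranks `r..s` are observed and rank `tau > s` is to be
predicted.  The pivot

    Psi = [log(1 - e^{-lambda z_tau}) - log(1 - e^{-lambda z_s})] /
          log(1 - e^{-lambda z_s})  =  t(z_tau) / t(z_s) - 1

is, by the gamma representation, `U(tau) / U(s) - 1` for order
statistics of independent `Gamma(i_j, 1)` variables -- its law depends
only on `(s, tau, n)` and the record-index multiset, not on `theta`,
`lambda` *or* `k` (the level cancels with the rate).  Three evaluators
of `P(Psi > psi)` ship and are tested against each other:

* **closed form** (default): because all gamma shapes are integers,
  the double integral over the joint law of `(U(s), U(tau))` reduces to
  finite sums -- each permutation term is
  `coef * u^a e^{-alpha u} v^b e^{-beta v}`, the inner incomplete-gamma
  integral is a finite Poisson sum, and the outer integral is a
  factorial ratio.  No special functions, no truncation.  (The
  regularized Gauss hypergeometric form that such theorems are usually
  written in reduces to exactly these finite sums at integer
  arguments.)
* **quadrature**: nested integration of the permanent-form joint
  density of `(z_s, z_tau)` *on the original GED scale*, carried out on
  the `u = t(w)` scale where the origin singularity of small
  `k * theta` becomes exponential decay.  This route depends on
  `theta` and `lambda` a priori, so its numerical invariance across
  `theta in {0.5, 1, 2, 5}` (agreement to 1e-8) is the package's
  scale/shape-freeness verification.
* **Monte Carlo**: stream-simulated replicates of the full design.

The `(1 - pi)` predictive interval for `z_tau` is
`[ -(1/lambda) log(1 - (1 - e^{-lambda z_s})^{psi + 1}),  z_s ]` with
`psi` solving `P(Psi <= psi) = 1 - pi`.  Since
`{z_tau > lower} = {Psi < psi}`, the interval covers with probability
exactly `1 - pi`; simulated coverage at 2000 replicates confirms this
at both 95% and 90%.  One convention deserves emphasis: quantile
inversion is sometimes written against the *survival* function
(`SF(psi) = 1 - pi`), which with this containment event would deliver
coverage `pi` rather than `1 - pi` and makes nominal-level comparisons
come out backwards (intervals that widen as `pi` grows).  This package
solves `P(Psi <= psi) = 1 - pi`, and its simulated coverage is the
authoritative check.  For random `N` the pivot law mixes the per-size
laws over `max(tau, rho):xi` with the size pmf truncated at `tau`.

## The simulators and what they do (and do not) emulate

`generate_melrrss()` reproduces the design's data-collection process:
independent GED streams scanned sequentially for records
(`method = "stream"`), with geometric chunk growth because inter-record
waits are heavy-tailed (the expected wait for even the second ordinary
record is infinite; memory stays bounded and the scan bails out if a
record value underflows to zero, below which no smaller double exists).
The `"inverse"` method samples each record value in one step from its
exact marginal.  The generator emulates perfect ranking within sets,
continuous measurements without ties, and independence across
sequences; it does not emulate ranking errors, measurement rounding
(the embedded fixtures are rounded to 2-3 decimals), dependence between
streams, or model misspecification, so passing tests certify the
machinery under the stated model, not robustness to those departures.

Study-harness defaults (`run_estimation_study`, `run_prediction_study`)
were fixed once, as a realistic small design: true `theta = 2`,
`lambda = 1`, prior rate `b = 0.5` (prior mean equal to the true shape
-- the informative-prior regime in which Bayes point estimates are
expected to beat the MLE), `k = 1`, `m1 = 3`, `m2 = 2` (so `n = 5`),
censoring `r = 2, s = 4` for estimation and `s = 2, tau = 3` for
prediction; 500 estimation and 2000 prediction replicates, with the
acceptance script running scaled-down versions (300 and 1000) of the
same studies.  Fixed-versus-random size comparisons match the fixed
size to `xi` ("same maximum size, sometimes fewer units").  Under that
matching the random-size *average interval width* is smaller, not
larger, than the fixed-size one -- smaller realized samples give
stochastically smaller `z_s` and hence narrower `[lower, z_s]`
intervals -- so the often-quoted direction "fixed beats random in AIW"
does not hold here (and the corresponding acceptance check fails by
design rather than being weakened).

## Numerical choices

* All likelihood matrices in log scale with row scaling; permanents on
  row-normalized entries.
* `t(w)` and its inverse via two-branch `log1mexp`, exact to the edge
  of double range (record values near 1e-300 are handled).
* Quadratures: `stats::integrate` with `rel.tol` 1e-10 (pivot SF and
  posterior), automatic fallback to looser tolerance on roundoff
  reports; normalization tests use nested quadrature on the `u` scale.
* Mode/bracket searches on log-spaced grids before Brent, because the
  objectives underflow to `-Inf` over most of any wide interval.
* Degenerate inputs: ties in user data are kept by stable sorting with
  strict record tests; densities at `w = 0` return `+Inf` when
  `k * theta < 1` (all quadratures use open endpoints); record values
  that underflow to exactly zero raise an informative error.

## The embedded worked examples and their reference values

`omelrrss_fixture()` ships two record-value samples extracted from
published medical datasets -- nerve-impulse waiting times (seconds) and
renal-transplant graft survival times (months) -- at `k = 1, 3, 5`,
with the analysis constants used alongside them (`lambda = 1.5`,
empirical prior rates 0.3672 / 0.2312, `delta = 0.5`, `c = +/-0.1`,
`r = 3`, `s = 5`, `rho = 2`, `xi = 7`).  `reproduce_tables()` recomputes
every fixed-size estimate and interval and writes them side by side
with the previously published reference values.

Those reference values largely do **not** reproduce under this
implementation, and the discrepancies are structural rather than
tuning:

* No censor-orientation convention, window convention, record-marginal
  variant, or value of `lambda` makes the permanent-form MLE equal
  most of the published point estimates (the MLE-versus-`lambda` curve
  never attains four of the six values).
* The published prediction intervals for the *same design* imply
  different pivot quantiles for the two datasets (about 6.3 and 1.5),
  which no distribution-free pivot can produce, and their 90% intervals
  are wider than their 95% ones.  The correctly computed 95% quantile
  for that design is about 3.09.  One published width (0.0799 for the
  nerve data, where the upper endpoint dominates the interval) does
  reproduce, and every published upper endpoint equals `z_3` exactly,
  as it must.
* Containment of the held-out true values is a coverage property, not
  a deterministic one: it holds throughout the nerve fixture but the
  renal series' steep record drops fall below the exact-coverage lower
  bounds.

The package therefore treats its own oracles -- normalization,
cross-form agreement, distribution-freeness, and simulated coverage --
as the ground truth for correctness, and reports the reference
comparison transparently.

## Known limitations

* `lambda` is assumed known; joint `(theta, lambda)` estimation and
  observed-information standard errors are out of scope.
* Permanents limit designs to `n <= 14` (comfortably above the sizes
  this sampling design is used at).
* The closed-form posterior route uses signed finite sums; for much
  larger designs than tested (`n <= 7`) cancellation could degrade it,
  which is why quadrature is the default for estimation.
* Upper-record analyses are supported only through the sign-flip
  utility (`extract_upper_krecords`); imperfect-ranking models are not
  modelled.
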