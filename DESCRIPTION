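Package: omelrrss
Title: Inference for the Generalized Exponential Distribution under
    Ordered Moving-Extremes Lower k-Record Ranked Set Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for lifetime inference when data are collected by
    moving-extremes ranked set sampling of lower k-record values
    (MELRRSS) and analysed through the ordered sample (OMELRRSS) under
    double type-II censoring, with either fixed or random sample sizes.
    Provides the generalized exponential distribution and the marginal
    distributions of i-th lower k-record values; samplers for the
    record-based design; the exact censored likelihood of the ordered,
    independent but non-identically distributed record values via matrix
    permanents, together with an equivalent series expansion; maximum
    likelihood, classical Bayes and empirical Bayes estimation of the
    shape parameter under squared-error, LINEX and balanced loss
    functions with an exponential prior; exact distribution-free pivotal
    prediction intervals for unobserved ordered values; and Monte Carlo
    harnesses for estimator comparison and prediction-interval coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, yaml
Config/testthat/edition: 3
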