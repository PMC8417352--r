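Package: stillbirthr
Title: Stillbirth Rate Estimation from Heterogeneous Surveillance Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating country-year stillbirth rates from
    heterogeneous data sources. Harmonises observations reported under
    alternative stillbirth definitions to the 28-weeks-gestation standard
    with propagated uncertainty, screens implausible datapoints with a
    probabilistic stillbirth-to-neonatal-mortality ratio test, fits a
    Bayesian hierarchical temporal sparse regression model (regularised
    horseshoe covariate shrinkage, country-specific B-spline smoothing,
    source-type biases and variances) by adaptive Hamiltonian Monte Carlo,
    and derives stillbirth counts, regional aggregates, annual rates of
    reduction and 90% uncertainty intervals. A synthetic-data generator
    reproduces the statistical structure the model assumes so the full
    pipeline can be validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
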