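Package: snakerisk
Title: Geostatistical Mapping of Snakebite Incidence from Community Survey Data
Version: 0.1.0
Authors@R:
    person("Snakerisk", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating and mapping the community incidence of
    snakebite and envenoming from stratified two-stage cluster surveys.
    Implements design-based incidence estimation with cluster-robust
    variances, exploratory Poisson regression with piecewise-linear (hinge)
    covariate effects and breakpoint selection, a geostatistical Poisson
    log-linear model with exponential (Matern kappa = 1/2) spatial
    correlation and a nugget fitted by Monte Carlo maximum likelihood,
    plug-in spatial prediction of the incidence surface, and
    exceedance-probability (probability contour) risk maps. A synthetic-data
    module generates country-like covariate surfaces, stratified cluster
    samples and Poisson counts over a latent Gaussian field so the whole
    pipeline can be exercised and tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
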