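# Synthetic-data generator: domain surfaces, stratified sampling, Gaussian
# fields, Poisson counts.

test_that("make_domain satisfies the grid contract and is seed-deterministic", {
  g <- make_domain(c(100, 100), 10, seed = 7)
  expect_s3_class(g, "covariate_grid")
  expect_equal(nrow(g), 100L)
  expect_true(all(is.finite(g$elevation)))
  expect_true(all(g$elevation >= 0 & g$elevation <= 2500))
  expect_true(all(g$population_density >= 0))
  expect_true(all(g$agri_proportion >= 0 & g$agri_proportion <= 1))
  expect_setequal(levels(g$climate_zone), c("dry", "intermediate", "wet"))
  expect_false(anyNA(g$climate_zone))

  g2 <- make_domain(c(100, 100), 10, seed = 7)
  expect_identical(g, g2)
  g3 <- make_domain(c(100, 100), 10, seed = 8)
  expect_false(isTRUE(all.equal(g$elevation, g3$elevation)))

  expect_error(make_domain(c(100, 100), -5), "resolution")
  expect_error(make_domain(c(100, 100), 13), "divide")
})

test_that("sample_clusters reproduces the 9-province / 125-cluster design", {
  g <- make_domain(c(240, 400), 8, seed = 1)
  s <- sample_clusters(g, n_strata = 9, clusters_per_stratum = 125, seed = 2)
  expect_equal(nrow(s$clusters), 1125L)
  expect_true(all(table(s$clusters$stratum) == 125L))
  expect_equal(nrow(s$design$strata), 9L)
  expect_true(all(s$design$strata$population > 0))
  expect_true(all(s$clusters$n_sampled > 0))
  # roughly the study's sampled persons per cluster
  expect_lt(abs(mean(s$clusters$n_sampled) - 148), 5)

  s2 <- sample_clusters(g, 9, 125, seed = 2)
  expect_identical(s$clusters, s2$clusters)

  # one cluster per stratum lands in distinct strata
  s1 <- sample_clusters(g, 4, 1, seed = 3)
  expect_equal(sort(unique(s1$clusters$stratum)), sort(s1$design$strata$stratum))

  expect_error(sample_clusters(g, 9, 10000, seed = 1), "cells")
})

test_that("simulate_field draws from the exponential-covariance process", {
  g <- make_domain(c(100, 100), 10, seed = 3)
  expect_equal(simulate_field(g, 0, 5, seed = 1), numeric(100))

  # replicate draws at one location: variance matches sigma2
  loc <- data.frame(x_km = 0, y_km = 0)
  v <- vapply(1:4000, function(s) simulate_field(loc, 0.19, 5, seed = s),
              numeric(1))
  expect_lt(abs(var(v) - 0.19), 3 * 0.19 * sqrt(2 / 4000))

  # two locations at distance phi: correlation ~ exp(-1)
  two <- data.frame(x_km = c(0, 5), y_km = c(0, 0))
  m <- vapply(1:4000, function(s) simulate_field(two, 1, 5, seed = s),
              numeric(2))
  expect_lt(abs(cor(m[1, ], m[2, ]) - exp(-1)), 0.05)

  # determinism
  f1 <- simulate_field(g, 0.5, 20, seed = 11)
  expect_identical(f1, simulate_field(g, 0.5, 20, seed = 11))
})

test_that("empirical variogram of simulated fields matches the model", {
  g <- make_domain(c(200, 200), 10, seed = 4)
  breaks <- c(0, 15, 45, 90)
  sv <- Reduce(`+`, lapply(1:6, function(s) {
    f <- simulate_field(g, sigma2 = 1, phi = 30, seed = s)
    empirical_variogram(f, g, breaks)$semivariance
  })) / 6
  # exact per-bin expectation: mean of 1 - exp(-d/phi) over the pairs that
  # fall in each bin (bin mids misrepresent the in-bin distance spread)
  d <- as.vector(stats::dist(as.matrix(g[, c("x_km", "y_km")])))
  bin <- cut(d, breaks, right = FALSE, labels = FALSE)
  theo <- tapply(1 - exp(-d / 30), bin, mean)
  expect_true(all(abs(sv - theo) / theo < 0.25))
})

test_that("simulate_counts follows the Poisson log-linear model", {
  spec <- model_spec("bites", "elevation")
  beta <- c("(Intercept)" = log(0.004), elevation = 0)
  cl <- data.frame(elevation = 0, climate_zone = "dry",
                   n_sampled = 25000)[rep(1, 1000), ]
  tm <- true_model(beta = beta, sigma2 = 0, phi = 1, tau2 = 0, spec = spec)
  cl <- simulate_counts(cl, tm, seed = 3)
  # expected count 100 per cluster; mean over 1000 within 3 SE
  expect_lt(abs(mean(cl$y_bites) - 100), 3 * sqrt(100 / 1000))
  # no latent noise: index of dispersion ~ 1
  expect_lt(abs(var(cl$y_bites) / mean(cl$y_bites) - 1), 0.15)

  # a large nugget overdisperses (lognormal-Poisson: VMR = 1 + mu(e^v - 1)e^v)
  tm2 <- true_model(beta = beta, sigma2 = 0, phi = 1, tau2 = 0.5, spec = spec)
  cl2 <- simulate_counts(cl[, setdiff(names(cl), "y_bites")], tm2, seed = 4)
  expect_gt(var(cl2$y_bites) / mean(cl2$y_bites), 5)

  expect_error(simulate_counts(transform(cl, n_sampled = 0), tm),
               "n_sampled")
})

test_that("generated cluster records pass the record invariants", {
  w <- small_world()
  expect_silent(validate_clusters(w$clusters))
  expect_true(all(w$clusters$y_envenoming <= w$clusters$y_bites))
})
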