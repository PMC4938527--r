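# Geostatistical model: covariance, variogram, latent-field MCMC, MCML.

test_that("exponential covariance evaluates and decays correctly", {
  expect_equal(exponential_cov(0, 2.5, 3), 2.5)
  expect_equal(exponential_cov(3, 1, 3), exp(-1))
  u <- seq(0, 500, by = 10)
  v <- exponential_cov(u, 1, 25)
  expect_true(all(diff(v) <= 0))
  expect_lt(v[length(v)], 1e-8)
  expect_error(exponential_cov(1, 1, 0), "phi")
  expect_error(exponential_cov(-1, 1, 1), ">= 0")
})

test_that("covariance matrices are symmetric positive semi-definite", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(10:40, 1)
    coords <- cbind(runif(n, 0, 300), runif(n, 0, 300))
    S <- exponential_cov(as.matrix(dist(coords)), runif(1, 0.05, 2),
                         runif(1, 0.5, 60))
    expect_equal(S, t(S))
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
  }
})

test_that("linear_predictor reproduces hand-evaluated published coefficients", {
  p <- published_geostat_params("bites")
  base <- data.frame(elevation = 0, climate_zone = "dry",
                     population_density = 0, agri_proportion = 0)
  expect_equal(linear_predictor(base, p$beta, p$spec), -6.6239)
  expect_equal(1e5 * exp(-6.6239), 132.7, tolerance = 1e-3)

  risky <- data.frame(elevation = 160, climate_zone = "wet",
                      population_density = 0, agri_proportion = 0.09)
  eta <- linear_predictor(risky, p$beta, p$spec)
  expect_equal(eta, -6.6239 + 0.0032 * 160 + 0.5586 + 7.2235 * 0.09)
  expect_equal(1e5 * exp(eta), 742, tolerance = 1e-3)

  pe <- published_geostat_params("envenoming")
  basee <- data.frame(elevation = 0, climate_zone = "dry",
                      population_density = 0)
  expect_equal(1e5 * exp(linear_predictor(basee, pe$beta, pe$spec)),
               226.3, tolerance = 1e-3)

  expect_error(linear_predictor(base[, -1], p$beta, p$spec))
})

test_that("empirical_variogram bins half squared differences", {
  one_pair <- empirical_variogram(c(0, 2),
                                  data.frame(x_km = c(0, 1), y_km = 0),
                                  breaks = c(0.5, 1.5))
  expect_equal(one_pair$semivariance, 2)
  expect_equal(one_pair$n_pairs, 1L)

  const <- empirical_variogram(rep(3, 10),
                               data.frame(x_km = 1:10, y_km = 0),
                               breaks = c(0, 3, 6, 12))
  expect_true(all(const$semivariance[const$n_pairs > 0] == 0))

  # iid unit-variance noise: sill ~ 1 in every bin
  set.seed(7)
  n <- 250
  coords <- data.frame(x_km = runif(n, 0, 100), y_km = runif(n, 0, 100))
  vg <- empirical_variogram(rnorm(n), coords, breaks = c(5, 20, 40, 70))
  expect_true(all(abs(vg$semivariance - 1) < 0.15))

  # empty bin: NA semivariance, zero pairs
  vg2 <- empirical_variogram(c(1, 2), data.frame(x_km = c(0, 1), y_km = 0),
                             breaks = c(5, 10))
  expect_true(is.na(vg2$semivariance))
  expect_equal(vg2$n_pairs, 0L)
})

test_that("sample_latent_field collapses, reproduces, and matches Laplace", {
  w <- small_world()
  cl <- w$clusters[1:30, ]
  ctl <- mcml_control(burnin = 100, thin = 2, n_draws = 100)
  beta_pub <- published_geostat_params("bites")$beta

  degenerate <- sample_latent_field(
    cl, list(beta = beta_pub, sigma2 = 0, phi = 1, tau2 = 0),
    bite_model_spec(), ctl, seed = 1)
  expect_true(all(degenerate$draws == 0))

  pr <- list(beta = beta_pub, sigma2 = 0.2, phi = 10, tau2 = 0.1)
  s1 <- sample_latent_field(cl, pr, bite_model_spec(), ctl, seed = 4)
  s2 <- sample_latent_field(cl, pr, bite_model_spec(), ctl, seed = 4)
  expect_identical(s1$draws, s2$draws)
  expect_true(all(is.finite(s1$draws)))

  # single-cluster toy with a large count: posterior ~ Gaussian around the
  # Laplace mode, computed here by direct 1-d optimisation
  one <- data.frame(x_km = 0, y_km = 0, elevation = 0, climate_zone = "dry",
                    population_density = 0, agri_proportion = 0,
                    n_sampled = 10000, y_bites = 60)
  spec1 <- model_spec("bites", "1")
  beta0 <- c("(Intercept)" = log(0.005))
  v <- 0.3
  mode <- optimize(function(t) 60 * t - 10000 * 0.005 * exp(t) - t^2 / (2 * v),
                   c(-3, 3), maximum = TRUE)$maximum
  ctl1 <- mcml_control(burnin = 500, thin = 2, n_draws = 1500)
  s3 <- sample_latent_field(one, list(beta = beta0, sigma2 = v, phi = 1,
                                      tau2 = 0), spec1, ctl1, seed = 6)
  draws <- s3$draws[, 1]
  mc_se <- sd(draws) / sqrt(length(draws) / 10)  # conservative ESS deflation
  expect_lt(abs(mean(draws) - mode), 3 * mc_se + 0.02)
})

test_that("fit_mcml matches the IRLS fit when variances vanish", {
  w <- small_world()
  f0 <- fit_mcml(w$clusters, bite_model_spec(),
                 fix = list(sigma2 = 0, tau2 = 0))
  g <- fit_glm(w$clusters, bite_model_spec())
  expect_lt(max(abs(f0$params$beta - g$coefficients)), 5e-4)
  expect_true(f0$converged)
})

test_that("fit_mcml improves the Monte Carlo likelihood and reports diagnostics", {
  fit <- small_fit()
  # objective is a log likelihood ratio against the anchor: >= 0 up to noise
  expect_gt(fit$loglik_ratio, -0.1)
  expect_true(fit$params$sigma2 >= 0 && fit$params$tau2 >= 0 &&
                fit$params$phi > 0)
  expect_true(is.matrix(fit$diagnostics$trace))
  expect_true(fit$diagnostics$acceptance > 0.1 &&
                fit$diagnostics$acceptance < 0.9)
  expect_true(all(fit$std_errors[seq_along(fit$params$beta)] > 0))
  ct <- coef_table(fit)
  expect_equal(ct$variable, names(fit$params$beta))
})
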