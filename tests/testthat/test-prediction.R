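# Plug-in prediction and exceedance maps.

# hand-made fit object with known parameters and latent draws
toy_fit <- function(sigma2 = 1, phi = 10, tau2 = 0, draws) {
  structure(list(
    params = list(beta = c("(Intercept)" = 0), sigma2 = sigma2, phi = phi,
                  tau2 = tau2),
    spec = model_spec("bites", "1"),
    samples = structure(list(draws = draws), class = "latent_field_samples"),
    converged = TRUE), class = "mcml_fit")
}

test_that("krige_conditional interpolates data locations and reverts to the prior", {
  w <- small_world()
  fit <- small_fit()
  cl <- w$clusters

  fit0 <- fit
  fit0$params$tau2 <- 0
  at_data <- krige_conditional(fit0, cl, cl[5, , drop = FALSE], seed = 1)
  expect_lt(max(abs(at_data[1, ] - fit$samples$draws[, 5])), 1e-3)

  far <- w$grid[1, , drop = FALSE]
  far$x_km <- 1e5
  far$y_km <- -1e5
  d_far <- krige_conditional(fit, cl, far, seed = 2)
  expect_lt(abs(mean(d_far)), 3 * sqrt(fit$params$sigma2 / ncol(d_far)) + 0.05)
  expect_lt(abs(var(as.vector(d_far)) - fit$params$sigma2),
            0.3 * fit$params$sigma2)
})

test_that("krige_conditional matches the closed-form Gaussian conditional", {
  # 3 data points on a line, one fixed latent draw, tau2 = 0: conditional
  # mean must equal c' Sigma^{-1} T and variance the kriging variance
  dloc <- data.frame(x_km = c(0, 10, 20), y_km = 0, n_sampled = 1,
                     cluster_id = c("a", "b", "c"))
  Tvec <- c(0.5, -0.2, 0.8)
  m <- 4000
  fit <- toy_fit(sigma2 = 1, phi = 10, tau2 = 0,
                 draws = matrix(Tvec, m, 3, byrow = TRUE))
  gloc <- data.frame(x_km = 5, y_km = 0)
  d <- krige_conditional(fit, dloc, gloc, seed = 3)

  S <- exp(-as.matrix(dist(c(0, 10, 20))) / 10)
  cvec <- exp(-abs(5 - c(0, 10, 20)) / 10)
  mu <- drop(cvec %*% solve(S, Tvec))
  v <- 1 - drop(cvec %*% solve(S, cvec))
  expect_equal(mean(d), mu, tolerance = 4 * sqrt(v / m) / abs(mu) + 1e-3)
  expect_equal(var(as.vector(d)), v, tolerance = 0.15)
})

test_that("incidence_surface is exact for degenerate draws and lognormal-correct", {
  w <- small_world()
  fit <- small_fit()
  grid <- as.data.frame(w$grid)[1:50, ]

  zero_draws <- matrix(0, 50, 200)
  attr(zero_draws, "grid") <- grid
  surf <- incidence_surface(fit, grid, zero_draws)
  eta <- linear_predictor(grid, fit$params$beta, fit$spec)
  expect_equal(surf$estimate, 1e5 * exp(eta))

  # lognormal mean: with S ~ N(m, v), E exp(S) = exp(m + v/2)
  set.seed(11)
  mv <- list(m = 0.3, v = 0.4)
  draws <- matrix(rnorm(20 * 8000, mv$m, sqrt(mv$v)), 20, 8000)
  attr(draws, "grid") <- grid[1:20, ]
  s2 <- incidence_surface(fit, grid[1:20, ], draws)
  expected <- 1e5 * exp(eta[1:20] + mv$m + mv$v / 2)
  expect_true(all(abs(s2$estimate / expected - 1) < 0.05))

  # permutation invariance
  perm <- sample(50)
  grid_p <- grid[perm, ]
  draws_p <- zero_draws[perm, ]
  attr(draws_p, "grid") <- grid_p
  surf_p <- incidence_surface(fit, grid_p, draws_p)
  expect_equal(surf_p$estimate[order(perm)], surf$estimate)
})

test_that("exceedance probabilities and PCM classes follow their contracts", {
  inc <- matrix(c(rep(500, 200), rep(100, 200)), 2, 200, byrow = TRUE)
  expect_equal(exceedance_probability(inc, 300), c(1, 0))
  expect_warning(exceedance_probability(inc[, 1:50], 300), "draws")

  set.seed(3)
  sym <- matrix(398 + rnorm(4000, 0, 50), 2, 2000)
  p <- exceedance_probability(sym, 398)
  expect_true(all(abs(p - 0.5) < 0.05))

  expect_equal(as.character(classify_pcm(c(0.70, 0.30, 0.5))),
               c("hot", "cold", "intermediate"))
  expect_error(classify_pcm(1.2), "0, 1")
})

test_that("threshold_suite maps are monotone and consistent with the surface", {
  w <- small_world()
  fit <- small_fit()
  d <- krige_conditional(fit, w$clusters, w$grid, seed = 5)
  em <- threshold_suite(fit, w$grid, d, c(300, 398, 500))
  expect_s3_class(em, "exceedance_maps")
  # hot fraction non-increasing, cold fraction non-decreasing in threshold
  expect_true(all(diff(em$summary$hot) <= 0))
  expect_true(all(diff(em$summary$cold) >= 0))
  # per-location monotonicity of exceedance probability
  expect_true(all(em$maps$p_300 >= em$maps$p_398 - 1e-12))
  expect_true(all(em$maps$p_398 >= em$maps$p_500 - 1e-12))
  # threshold zero: certain exceedance
  em0 <- threshold_suite(fit, w$grid, d, 0)
  expect_true(all(em0$maps$p_0 == 1))
  # rank consistency between the point surface and mid-threshold probability
  expect_gt(cor(em$maps$estimate, em$maps$p_398, method = "spearman"), 0.95)
})

test_that("a planted high-incidence island is classified hot", {
  # island = 3x the background incidence in a corner of the domain;
  # moderately strong data so the posterior sees it clearly
  for (s in 1:3) {
    g <- make_domain(c(120, 120), 20, seed = s)
    samp <- sample_clusters(g, 4, 9, persons_per_cluster_mean = 2000, seed = s)
    cl <- samp$clusters
    island <- cl$x_km <= 40 & cl$y_km <= 40
    eta <- log(400 / 1e5) + log(3) * island
    cl$y_bites <- with_seed_test(s, rpois(nrow(cl), cl$n_sampled * exp(eta)))
    ctl <- mcml_control(burnin = 200, thin = 2, n_draws = 300,
                        max_anchors = 2, se = FALSE)
    fit <- suppressWarnings(fit_mcml(cl, model_spec("bites", "1"),
                                     init = list(beta = c("(Intercept)" = log(4e-3)),
                                                 sigma2 = 0.3, phi = 25,
                                                 tau2 = 0.05),
                                     control = ctl, seed = s))
    gi <- data.frame(x_km = 20, y_km = 20, elevation = 0,
                     climate_zone = "dry", population_density = 0,
                     agri_proportion = 0)
    d <- krige_conditional(fit, cl, gi, seed = s)
    em <- threshold_suite(fit, gi, d, 398)
    expect_equal(em$maps$class_398, "hot")
  }
})
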