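# Exploratory Poisson regression with hinge terms.

test_that("hinge basis behaves at, below and above the knot", {
  expect_equal(hinge(200, 160), 40)
  expect_equal(hinge(100, 160), 0)
  expect_equal(hinge(160, 160), 0)
  expect_equal(hinge_basis(c(100, 200), 160),
               cbind(x = c(100, 200), hinge = c(0, 40)))
  expect_error(hinge(NaN, 160), "finite")
})

test_that("fit_glm recovers closed-form and simulated truths", {
  # intercept-only Poisson MLE: log(sum y / sum n)
  cl <- data.frame(y_bites = c(2, 3, 5), n_sampled = c(1000, 1000, 1000),
                   climate_zone = "dry")
  f <- fit_glm(cl, model_spec("bites", "1"))
  expect_equal(unname(f$coefficients), log(10 / 3000), tolerance = 1e-8)

  # saturated model fits exactly
  cl2 <- data.frame(y_bites = c(3, 7), n_sampled = c(100, 100),
                    elevation = c(0, 50))
  f2 <- fit_glm(cl2, model_spec("bites", "elevation"))
  expect_lt(f2$deviance, 1e-8)

  # parameter recovery at sigma2 = tau2 = 0
  beta <- c("(Intercept)" = -6.0, elevation = 0.002,
            climate_zoneintermediate = 0.2, climate_zonewet = 0.5)
  spec <- model_spec("bites", c("elevation", "climate_zone"))
  cl3 <- nonspatial_clusters(1000, beta, spec, n_sampled = 2000, seed = 21)
  f3 <- fit_glm(cl3, spec)
  se <- sqrt(diag(f3$vcov))
  expect_true(all(abs(f3$coefficients - beta[names(f3$coefficients)]) <
                    3 * se))
})

test_that("select_breakpoint recovers a true knot and flags flat profiles", {
  beta <- c("(Intercept)" = -6.2, elevation = 0.0032,
            "hinge(elevation, 160)" = -0.0046)
  spec <- model_spec("bites", c("elevation", "hinge(elevation, 160)"))
  # dense support on both sides of the knot
  set.seed(31)
  cl <- data.frame(elevation = runif(600, 0, 400), n_sampled = 10000)
  cl <- simulate_counts(cl, true_model(beta = beta, sigma2 = 0, phi = 1,
                                       tau2 = 0, spec = spec), seed = 31)
  sel <- select_breakpoint(cl, spec, "elevation", seq(120, 200, by = 5))
  expect_s3_class(sel, "piecewise_spec")
  expect_lte(abs(sel$knot - 160), 5)
  expect_equal(nrow(sel$profile), 17L)

  # single candidate is returned as-is
  sel1 <- select_breakpoint(cl, spec, "elevation", 150)
  expect_equal(sel1$knot, 150)

  # purely linear truth: profile flat within noise (no deep interior minimum)
  beta_lin <- c("(Intercept)" = -6.2, elevation = 0.001)
  cl_lin <- nonspatial_clusters(500, beta_lin, model_spec("bites", "elevation"),
                                n_sampled = 5000, seed = 32)
  sel_lin <- select_breakpoint(cl_lin, model_spec("bites", "elevation"),
                               "elevation", seq(120, 200, by = 10))
  # the best hinge must not beat the plain linear fit by more than the
  # chi-square noise of one spare parameter scanned over the grid
  dev_lin <- fit_glm(cl_lin, model_spec("bites", "elevation"))$deviance
  expect_lt(dev_lin - min(sel_lin$profile$deviance, na.rm = TRUE), 15)

  expect_error(select_breakpoint(cl, spec, "elevation", c(-50, 0)), "range")
})

test_that("hinge with knot near the data maximum reproduces the linear fit", {
  beta_lin <- c("(Intercept)" = -6.2, elevation = 0.001)
  cl <- nonspatial_clusters(300, beta_lin, model_spec("bites", "elevation"),
                            n_sampled = 5000, seed = 33)
  k <- max(cl$elevation)
  f_lin <- fit_glm(cl, model_spec("bites", "elevation"))
  f_h <- fit_glm(cl, model_spec("bites", c(
    "elevation", sprintf("hinge(elevation, %.10g)", k))))
  # the hinge column is identically zero and gets aliased out
  expect_length(f_h$aliased, 1L)
  expect_equal(f_h$deviance, f_lin$deviance)
  expect_equal(f_h$coefficients[["elevation"]],
               f_lin$coefficients[["elevation"]])
})

test_that("standardized residuals are Pearson residuals at cluster locations", {
  # equal counts under an intercept-only fit: residuals exactly zero
  cl <- data.frame(y_bites = rep(2, 4), n_sampled = rep(1000, 4),
                   x_km = 1:4, y_km = 1)
  f <- fit_glm(cl, model_spec("bites", "1"))
  r <- standardized_residuals(cl, f)
  expect_equal(r$residual, rep(0, 4))
  expect_false(any(r$undefined))

  # hand arithmetic: y = (4, 0), fitted mean 2 -> residuals +-2/sqrt(2)
  cl_h <- data.frame(y_bites = c(4, 0), n_sampled = c(1000, 1000),
                     x_km = c(0, 1), y_km = 0)
  f_h <- fit_glm(cl_h, model_spec("bites", "1"))
  r_h <- standardized_residuals(cl_h, f_h)
  expect_equal(r_h$residual, c(sqrt(2), -sqrt(2)), tolerance = 1e-8)

  # null simulation: mean residual near zero
  beta <- c("(Intercept)" = -6.0)
  cl2 <- nonspatial_clusters(800, beta, model_spec("bites", "1"),
                             n_sampled = 3000, seed = 41)
  f2 <- fit_glm(cl2, model_spec("bites", "1"))
  r2 <- standardized_residuals(cl2, f2)
  expect_lt(abs(mean(r2$residual)), 0.1)
})
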