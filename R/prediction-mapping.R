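# Plug-in spatial prediction and exceedance-probability ("probability
# contour") mapping. Covariance parameters are fixed at their MCML point
# estimates; prediction uncertainty comes from the retained MCMC draws of
# the latent field and the exact conditional Gaussian at grid locations.
# The predictive target is the spatially structured incidence
# exp(beta'd(x) + S(x)); the nugget Z is cluster-level extra noise and is
# excluded (set `include_nugget = TRUE` to add it back).

#' Conditional simulation of the latent surface at grid locations
#'
#' For each retained draw of `T = S + Z` at the data locations, draws
#' `S(grid)` from the exact conditional Gaussian given that draw, with
#' covariance parameters plugged in from the fit:
#' `S(g) | T ~ N(c' Sigma_T^{-1} T, sigma2 R_gg - c' Sigma_T^{-1} c)` where
#' `c = sigma2 R_gd` and `Sigma_T = sigma2 R_dd + tau2 I`.
#'
#' @param fit an `mcml_fit`.
#' @param clusters the cluster table the model was fitted to.
#' @param grid prediction grid with `x_km`, `y_km` and the spec's covariates;
#'   rows with missing covariates are masked (dropped, with their indices in
#'   attribute `masked`).
#' @param samples optional [sample_latent_field()] output (defaults to the
#'   draws stored in the fit).
#' @param include_nugget add independent `N(0, tau2)` noise per draw and
#'   location, making the target the cluster-level incidence instead of the
#'   smooth surface.
#' @param seed integer seed for the conditional noise.
#' @return matrix of conditional draws (grid rows x draws), with attributes
#'   `masked` (dropped row indices) and `grid` (the kept grid rows).
#' @export
krige_conditional <- function(fit, clusters, grid, samples = fit$samples,
                              include_nugget = FALSE, seed = 1) {
  stopifnot(inherits(fit, "mcml_fit"))
  if (is.null(samples)) stopf("no latent-field samples available")
  pr <- fit$params
  covars <- setdiff(all.vars(spec_formula(fit$spec, FALSE)), "")
  keep <- if (length(covars)) {
    stats::complete.cases(as.data.frame(grid)[, covars, drop = FALSE])
  } else rep(TRUE, nrow(as.data.frame(grid)))
  masked <- which(!keep)
  grid_kept <- as.data.frame(grid)[keep, , drop = FALSE]
  gc_ <- as.matrix(grid_kept[, c("x_km", "y_km")])
  dc <- as.matrix(clusters[, c("x_km", "y_km")])
  G <- nrow(gc_); m <- nrow(samples$draws)

  if (pr$sigma2 < 1e-12) {
    out <- matrix(0, G, m)
  } else {
    SigT <- latent_cov(dc, pr$sigma2, pr$phi, pr$tau2)
    cgd <- exponential_cov(cross_dist(gc_, dc), pr$sigma2, pr$phi)
    A <- cgd %*% chol2inv(chol(SigT))            # G x n
    Mu <- A %*% t(samples$draws)                 # G x m conditional means
    V <- exponential_cov(cross_dist(gc_, gc_), pr$sigma2, pr$phi) -
      tcrossprod(A, cgd)
    V <- (V + t(V)) / 2
    diag(V) <- pmax(diag(V), 0) + 1e-10 * pr$sigma2
    Lv <- chol(V)
    out <- with_seed(split_seed(seed, "krige"), {
      Mu + crossprod(Lv, matrix(stats::rnorm(G * m), G, m))
    })
  }
  if (include_nugget && pr$tau2 > 0) {
    out <- out + with_seed(split_seed(seed, "nugget"), {
      matrix(stats::rnorm(G * m, 0, sqrt(pr$tau2)), G, m)
    })
  }
  attr(out, "masked") <- masked
  attr(out, "grid") <- grid_kept
  out
}

#' Predicted incidence surface
#'
#' Point estimate per grid location: the mean over conditional draws of
#' `exp(beta'd(x) + S(x))`, reported per 100 000 person-years. Averaging the
#' exponentiated draws (rather than exponentiating the mean) makes the
#' estimate unbiased for incidence under the lognormal conditional.
#'
#' @param fit an `mcml_fit`.
#' @param grid the prediction grid passed to [krige_conditional()].
#' @param draws conditional draws from [krige_conditional()].
#' @return data.frame `x_km`, `y_km`, `estimate`, `q025`, `q50`, `q975`
#'   (all per 100 000), one row per unmasked grid location.
#' @export
incidence_surface <- function(fit, grid, draws) {
  grid_kept <- attr(draws, "grid") %||% as.data.frame(grid)
  eta <- linear_predictor(grid_kept, fit$params$beta, fit$spec)
  inc <- 1e5 * exp(sweep(draws, 1, eta, "+"))
  qs <- t(apply(inc, 1, stats::quantile, c(0.025, 0.5, 0.975)))
  data.frame(x_km = grid_kept$x_km, y_km = grid_kept$y_km,
             estimate = rowMeans(inc),
             q025 = qs[, 1], q50 = qs[, 2], q975 = qs[, 3])
}

# incidence draws per 1e5 at grid locations (internal shared path)
incidence_draws <- function(fit, grid, draws) {
  grid_kept <- attr(draws, "grid") %||% as.data.frame(grid)
  eta <- linear_predictor(grid_kept, fit$params$beta, fit$spec)
  1e5 * exp(sweep(draws, 1, eta, "+"))
}

#' Exceedance probability per location
#'
#' The fraction of conditional draws whose incidence exceeds the threshold:
#' the Monte Carlo estimate of `P(incidence(x) > t | data)`.
#'
#' @param inc_draws incidence draws per 100 000 (locations x draws), e.g.
#'   from the internal surface machinery or any matrix of draws.
#' @param threshold incidence threshold per 100 000 (> 0 allowed; 0 gives
#'   probability 1 everywhere).
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
exceedance_probability <- function(inc_draws, threshold) {
  assert_scalar_num(threshold, "threshold", 0)
  if (ncol(inc_draws) < 100) {
    warning("fewer than 100 draws; exceedance probabilities are noisy",
            call. = FALSE)
  }
  rowMeans(inc_draws > threshold)
}

#' Classify exceedance probabilities into risk classes
#'
#' The probability-contour-map rule: probability at least `high` (default
#' 0.7) is a hotspot ("hot"), at most `low` (default 0.3) a cold spot
#' ("cold"), anything strictly between is "intermediate". Both boundaries
#' are inclusive.
#'
#' @param probabilities numeric in \[0, 1\].
#' @param low,high class boundaries.
#' @return factor with levels cold < intermediate < hot.
#' @export
classify_pcm <- function(probabilities, low = 0.3, high = 0.7) {
  if (any(!is.finite(probabilities)) || any(probabilities < 0) ||
      any(probabilities > 1)) {
    stopf("probabilities must lie in [0, 1]")
  }
  out <- rep("intermediate", length(probabilities))
  out[probabilities >= high] <- "hot"
  out[probabilities <= low] <- "cold"
  factor(out, levels = c("cold", "intermediate", "hot"))
}

#' Exceedance maps for a set of thresholds
#'
#' Builds one exceedance-probability map per threshold from shared
#' conditional draws, with the hot/cold/intermediate classification and a
#' summary of class area fractions. Published usage: bite thresholds
#' 300/398/500 per 100 000 around the national rate 398, envenoming
#' thresholds 100/151/250 around 151.
#'
#' @param fit an `mcml_fit`.
#' @param grid prediction grid.
#' @param draws conditional draws from [krige_conditional()].
#' @param thresholds positive numeric vector, per 100 000.
#' @param low,high classification boundaries (see [classify_pcm()]).
#' @return object of class `exceedance_maps`: `maps` (data.frame with
#'   coordinates, estimate, and `p_<t>` / `class_<t>` columns per
#'   threshold), `summary` (class fractions by threshold), `thresholds`.
#' @export
threshold_suite <- function(fit, grid, draws, thresholds,
                            low = 0.3, high = 0.7) {
  if (any(thresholds < 0)) stopf("thresholds must be positive")
  inc <- incidence_draws(fit, grid, draws)
  surf <- incidence_surface(fit, grid, draws)
  maps <- surf[, c("x_km", "y_km", "estimate")]
  summ <- list()
  for (t in thresholds) {
    p <- exceedance_probability(inc, t)
    cl <- classify_pcm(p, low, high)
    maps[[sprintf("p_%g", t)]] <- p
    maps[[sprintf("class_%g", t)]] <- as.character(cl)
    frac <- prop.table(table(cl))
    summ[[length(summ) + 1L]] <- data.frame(
      threshold = t, cold = as.numeric(frac["cold"]),
      intermediate = as.numeric(frac["intermediate"]),
      hot = as.numeric(frac["hot"]))
  }
  structure(list(maps = maps, summary = do.call(rbind, summ),
                 thresholds = thresholds),
            class = "exceedance_maps")
}

#' @export
print.exceedance_maps <- function(x, ...) {
  cat("Exceedance maps at thresholds (per 100 000):",
      paste(x$thresholds, collapse = ", "), "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
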