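# Synthetic world generator: country-like covariate surfaces, a stratified
# multistage cluster sample, latent spatially correlated fields, and Poisson
# outcome counts. Gives every downstream stage a fully reproducible input
# with the statistical structure the analysis assumes.

#' Generate a country-like covariate grid
#'
#' Builds a regular grid of cell centroids over a rectangular domain with
#' four covariate surfaces: a smooth elevation surface (a fixed number of
#' seeded Gaussian bumps rescaled to \[0, 2400\] m, mimicking a coastal
#' plain with interior mountains), a log-normal population density that
#' decays with elevation, a proportion of agricultural workers
#' anti-correlated with density, and three contiguous climate zones (dry /
#' intermediate / wet bands from west to east).
#'
#' @param extent_km length-2 numeric, domain size in km.
#' @param resolution_km cell size in km; must divide both extents.
#' @param seed integer master seed.
#' @return data.frame of class `covariate_grid` with columns `x_km`, `y_km`,
#'   `elevation`, `population_density`, `agri_proportion`, `climate_zone`;
#'   attributes `extent_km` and `resolution_km`.
#' @examples
#' g <- make_domain(c(100, 100), 10, seed = 7)
#' nrow(g)  # 100 cells
#' @export
make_domain <- function(extent_km = c(240, 400), resolution_km = 10,
                        seed = 1) {
  if (length(extent_km) != 2L || any(!is.finite(extent_km)) ||
      any(extent_km <= 0)) {
    stopf("`extent_km` must be two positive numbers")
  }
  assert_scalar_num(resolution_km, "resolution_km", 0, strict_lower = TRUE)
  n_cells <- extent_km / resolution_km
  if (any(abs(n_cells - round(n_cells)) > 1e-8)) {
    stopf("`resolution_km` must divide both extents")
  }
  n_cells <- round(n_cells)
  xs <- seq(resolution_km / 2, by = resolution_km, length.out = n_cells[1])
  ys <- seq(resolution_km / 2, by = resolution_km, length.out = n_cells[2])
  grid <- expand.grid(x_km = xs, y_km = ys, KEEP.OUT.ATTRS = FALSE)

  with_seed(split_seed(seed, "domain"), {
    # elevation: sum of Gaussian bumps, highest towards the domain interior
    n_bumps <- 6L
    cx <- stats::runif(n_bumps, 0.25, 0.75) * extent_km[1]
    cy <- stats::runif(n_bumps, 0.25, 0.75) * extent_km[2]
    w <- stats::runif(n_bumps, 0.08, 0.25) * mean(extent_km)
    h <- stats::runif(n_bumps, 0.3, 1)
    elev <- rowSums(vapply(seq_len(n_bumps), function(b) {
      h[b] * exp(-((grid$x_km - cx[b])^2 + (grid$y_km - cy[b])^2) /
                   (2 * w[b]^2))
    }, numeric(nrow(grid))))
    elev <- 2400 * (elev - min(elev)) / max(elev - min(elev))

    # density: log-normal, lower at altitude, with mild spatial noise
    dens <- exp(stats::rnorm(nrow(grid), mean = 5.2 - elev / 900, sd = 0.7))

    # agricultural share: falls with density; spread wide enough that both
    # near-zero (urban) and ~50% (farming) communities occur, so the 9%
    # breakpoint sits inside the data range
    ld <- log1p(dens)
    z <- -0.4 - 1.5 * (ld - mean(ld)) / stats::sd(ld) +
      stats::rnorm(nrow(grid), 0, 0.8)
    agri <- 0.5 * stats::plogis(z)

    thirds <- extent_km[1] * c(1, 2) / 3
    zone <- cut(grid$x_km, c(-Inf, thirds, Inf), labels = climate_levels)
    zone <- factor(as.character(zone), levels = climate_levels)

    grid$elevation <- elev
    grid$population_density <- dens
    grid$agri_proportion <- agri
    grid$climate_zone <- zone
  })
  structure(grid, extent_km = extent_km, resolution_km = resolution_km,
            class = c("covariate_grid", "data.frame"))
}

#' Draw a stratified cluster sample from a covariate grid
#'
#' Partitions the grid cells into `n_strata` contiguous strata of (near)
#' equal cell count, then samples `clusters_per_stratum` distinct cells per
#' stratum by simple random sampling. Each sampled cell becomes one survey
#' cluster inheriting the cell's covariates; its sampled population is drawn
#' Poisson around `persons_per_cluster_mean` (default 148, the per-cluster
#' average of a survey of 165665 people in 1118 clusters of ~40 households).
#'
#' @param grid a [make_domain()] grid.
#' @param n_strata number of strata (provinces); default 9.
#' @param clusters_per_stratum clusters sampled in each stratum; default 125.
#' @param persons_per_cluster_mean mean sampled persons per cluster.
#' @param seed integer master seed.
#' @return list with `clusters` (data.frame of cluster records, counts
#'   unset) and `design` (a [survey_design()]).
#' @export
sample_clusters <- function(grid, n_strata = 9, clusters_per_stratum = 125,
                            persons_per_cluster_mean = 148, seed = 1) {
  stopifnot(inherits(grid, "covariate_grid"))
  assert_scalar_num(n_strata, "n_strata", 1)
  assert_scalar_num(persons_per_cluster_mean, "persons_per_cluster_mean", 0,
                    strict_lower = TRUE)
  stratum_of <- grid_strata(grid, n_strata)
  per_stratum <- table(stratum_of)
  if (clusters_per_stratum > min(per_stratum)) {
    stopf("requested %d clusters per stratum but the smallest stratum has %d cells",
          clusters_per_stratum, min(per_stratum))
  }
  cell_area <- attr(grid, "resolution_km")^2
  pop_totals <- round(tapply(grid$population_density, stratum_of, sum) *
                        cell_area)

  idx <- with_seed(split_seed(seed, "clusters"), {
    unlist(lapply(levels(stratum_of), function(s) {
      cells <- which(stratum_of == s)
      sort(sample(cells, clusters_per_stratum))
    }))
  })
  clusters <- as.data.frame(grid[idx, , drop = FALSE])
  clusters$stratum <- as.character(stratum_of[idx])
  clusters$cluster_id <- sprintf("%s_C%04d", clusters$stratum,
                                 as.integer(stats::ave(idx, clusters$stratum,
                                                       FUN = seq_along)))
  clusters$n_sampled <- with_seed(split_seed(seed, "population"), {
    pmax(1L, stats::rpois(nrow(clusters), persons_per_cluster_mean))
  })
  rownames(clusters) <- NULL
  design <- survey_design(data.frame(stratum = names(pop_totals),
                                     population = as.numeric(pop_totals)))
  list(clusters = clusters, design = design)
}

#' Partition grid cells into survey strata
#'
#' Contiguous strata of near-equal cell count, swept column-major from west
#' to east. This is the stratification [sample_clusters()] uses, exposed so
#' that design-based estimands (e.g. per-stratum mean incidence over all
#' cells) can be computed against the same partition.
#'
#' @param grid a [make_domain()] grid.
#' @param n_strata number of strata.
#' @return factor of stratum labels, one per grid row.
#' @export
grid_strata <- function(grid, n_strata) {
  ord <- order(grid$x_km, grid$y_km)
  rank <- integer(nrow(grid))
  rank[ord] <- seq_len(nrow(grid))
  lab <- sprintf("P%02d", ceiling(rank * n_strata / nrow(grid)))
  factor(lab)
}

#' Simulate a zero-mean Gaussian field with exponential covariance
#'
#' One exact draw of S ~ N(0, sigma2 * exp(-u / phi)) at the given
#' locations, via Cholesky factorisation of the full covariance matrix (a
#' small diagonal jitter guards against numerically semi-definite cases).
#' The exponential model is the Matern family with smoothness 1/2.
#'
#' @param locations matrix or data.frame with columns `x_km`, `y_km`.
#' @param sigma2 spatial variance (>= 0; 0 returns the zero field).
#' @param phi correlation range in km (> 0).
#' @param seed integer seed.
#' @return numeric vector of field values.
#' @export
simulate_field <- function(locations, sigma2, phi, seed = 1) {
  coords <- as.matrix(as.data.frame(locations)[, c("x_km", "y_km")])
  assert_scalar_num(sigma2, "sigma2", 0)
  assert_scalar_num(phi, "phi", 0, strict_lower = TRUE)
  n <- nrow(coords)
  if (sigma2 == 0) return(numeric(n))
  S <- exponential_cov(cross_dist(coords, coords), sigma2, phi)
  diag(S) <- diag(S) + 1e-10 * sigma2
  L <- tryCatch(chol(S), error = function(e) {
    stopf("covariance matrix not positive definite after jitter")
  })
  with_seed(split_seed(seed, "field"), drop(crossprod(L, stats::rnorm(n))))
}

#' Parameters of the generative model
#'
#' Bundles the log-linear coefficients and covariance parameters that drive
#' [simulate_counts()]. Defaults are the published snakebite fit
#' ([published_geostat_params()]), so synthetic worlds live on the published
#' scale.
#'
#' @param beta named coefficient vector matching `spec`'s design columns.
#' @param sigma2,phi,tau2 spatial variance, range (km) and nugget variance.
#' @param spec the [model_spec()] whose design `beta` multiplies.
#' @return list of class `true_model`.
#' @export
true_model <- function(beta = published_geostat_params("bites")$beta,
                       sigma2 = 0.189, phi = 0.091, tau2 = 0.304,
                       spec = bite_model_spec()) {
  assert_scalar_num(sigma2, "sigma2", 0)
  assert_scalar_num(phi, "phi", 0, strict_lower = TRUE)
  assert_scalar_num(tau2, "tau2", 0)
  structure(list(beta = beta, sigma2 = sigma2, phi = phi, tau2 = tau2,
                 spec = spec),
            class = "true_model")
}

#' Simulate Poisson outcome counts over a latent field
#'
#' Draws `count_i ~ Poisson(n_i * exp(beta' d_i + S_i + Z_i))` with
#' `Z_i ~ N(0, tau2)` independent cluster-level noise, where `S` is a field
#' draw at the cluster locations (e.g. from [simulate_field()]).
#'
#' @param clusters cluster table with covariates and `n_sampled`.
#' @param model a [true_model()].
#' @param field numeric vector S, one value per cluster (default all zero).
#' @param seed integer seed.
#' @param response which count column to fill (defaults to the spec's).
#' @return `clusters` with the response count column filled in.
#' @export
simulate_counts <- function(clusters, model = true_model(), field = NULL,
                            seed = 1, response = NULL) {
  stopifnot(inherits(model, "true_model"))
  if (any(clusters$n_sampled <= 0)) stopf("all n_sampled must be > 0")
  n <- nrow(clusters)
  if (is.null(field)) field <- numeric(n)
  if (length(field) != n) stopf("field length != number of clusters")
  eta <- linear_predictor(clusters, model$beta, model$spec) + field
  if (any(!is.finite(eta))) stopf("non-finite linear predictor")
  ycol <- if (is.null(response)) response_column(model$spec)
          else response_column(model_spec(response, "elevation"))
  with_seed(split_seed(seed, "counts"), {
    z <- if (model$tau2 > 0) stats::rnorm(n, 0, sqrt(model$tau2)) else 0
    clusters[[ycol]] <- stats::rpois(n, clusters$n_sampled * exp(eta + z))
  })
  clusters
}

#' Simulate a complete synthetic survey
#'
#' Runs the whole generative chain: covariate domain, stratified cluster
#' sample, latent fields, and counts for both responses. Snakebite counts
#' follow the bite model; envenoming counts are binomial thinnings of the
#' bite counts with per-cluster probability
#' `min(1, exp(eta_env - eta_bite))`, which preserves the envenoming
#' marginal Poisson rate wherever the envenoming rate is below the bite rate
#' and guarantees the record invariant `y_envenoming <= y_bites`.
#'
#' @param seed integer master seed.
#' @param n_strata,clusters_per_stratum,persons_per_cluster_mean design knobs
#'   (defaults: the 9-province, 125-cluster, ~148-person design).
#' @param extent_km,resolution_km domain knobs.
#' @param bite_model,envenoming_model [true_model()]s for the two responses.
#' @return list `grid`, `clusters`, `design`, `field` (bite-field draw).
#' @export
simulate_survey <- function(seed = 1, n_strata = 9, clusters_per_stratum = 125,
                            persons_per_cluster_mean = 148,
                            extent_km = c(240, 400), resolution_km = 10,
                            bite_model = true_model(),
                            envenoming_model = true_model(
                              beta = published_geostat_params("envenoming")$beta,
                              sigma2 = 0.055475, phi = 0.129351,
                              tau2 = 0.247201,
                              spec = envenoming_model_spec())) {
  grid <- make_domain(extent_km, resolution_km, seed = seed)
  samp <- sample_clusters(grid, n_strata, clusters_per_stratum,
                          persons_per_cluster_mean, seed = seed)
  cl <- samp$clusters
  S_b <- simulate_field(cl, bite_model$sigma2, bite_model$phi,
                        seed = split_seed(seed, "bite-field"))
  cl <- simulate_counts(cl, bite_model, S_b, seed = split_seed(seed, "bites"))

  S_e <- simulate_field(cl, envenoming_model$sigma2, envenoming_model$phi,
                        seed = split_seed(seed, "env-field"))
  eta_b <- linear_predictor(cl, bite_model$beta, bite_model$spec) + S_b
  eta_e <- linear_predictor(cl, envenoming_model$beta,
                            envenoming_model$spec) + S_e
  p <- pmin(1, exp(eta_e - eta_b))
  cl$y_envenoming <- with_seed(split_seed(seed, "envenoming"), {
    stats::rbinom(nrow(cl), cl$y_bites, p)
  })
  list(grid = grid, clusters = cl, design = samp$design, field = S_b)
}
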