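# Non-spatial exploratory modelling: Poisson GLM with an offset for the
# sampled population, piecewise-linear (hinge) covariate effects, breakpoint
# selection by a deviance scan, and Pearson residuals for the variogram.

#' Hinge (piecewise-linear) basis term
#'
#' `hinge(x, knot)` is `max(0, x - knot)`: adding it next to the linear term
#' lets the slope change at `knot` while the fit stays continuous. Usable
#' directly inside model formulas.
#'
#' @param x numeric vector.
#' @param knot numeric scalar, in the units of `x`.
#' @return numeric vector, zero at and below the knot.
#' @examples
#' hinge(c(100, 160, 200), 160)  # 0 0 40
#' @export
hinge <- function(x, knot) {
  if (!is.numeric(x) || any(!is.finite(x))) stopf("hinge(): non-finite x")
  assert_scalar_num(knot, "knot")
  pmax(0, x - knot)
}

#' Two-column hinge basis
#'
#' Returns the pair `(x, max(0, x - knot))` whose coefficients are the slope
#' below the knot and the change in slope above it.
#'
#' @inheritParams hinge
#' @return matrix with columns `x` and `hinge`.
#' @export
hinge_basis <- function(x, knot) {
  cbind(x = x, hinge = hinge(x, knot))
}

climate_levels <- c("dry", "intermediate", "wet")

#' Declarative model specification
#'
#' Describes which response a count model explains and through which terms.
#' Terms are given as right-hand-side formula strings: plain covariate names,
#' `hinge(var, knot)` for a slope change at `knot`, or a categorical such as
#' `climate_zone` (dummy-coded against the dry zone). The offset is always
#' the log sampled population, so coefficients are on the log incidence
#' (events per person-year) scale.
#'
#' @param response `"bites"` or `"envenoming"` (column `y_bites` /
#'   `y_envenoming` of a cluster table).
#' @param terms character vector of term labels.
#' @return object of class `model_spec`.
#' @examples
#' model_spec("bites", c("elevation", "hinge(elevation, 160)", "climate_zone"))
#' @export
model_spec <- function(response = c("bites", "envenoming"), terms) {
  response <- match.arg(response)
  if (!is.character(terms) || length(terms) < 1L) {
    stopf("`terms` must be a non-empty character vector")
  }
  structure(list(response = response, terms = terms), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Count model spec\n  response:", x$response,
      "\n  offset:   log(n_sampled)\n  terms:   ",
      paste(x$terms, collapse = " + "), "\n")
  invisible(x)
}

#' Default model specifications
#'
#' `bite_model_spec()` carries the published snakebite covariate set:
#' elevation with a slope change at 160 m, climate zone, population density,
#' and the proportion of agricultural workers with a slope change at 0.09.
#' `envenoming_model_spec()` uses the spatial variables only (elevation with
#' a 195 m knot, climate zone, population density), reflecting the view that
#' envenoming follows the distribution of venomous snakes rather than
#' human-snake contact.
#'
#' @return a [model_spec()].
#' @export
bite_model_spec <- function() {
  model_spec("bites", c(
    "elevation", "hinge(elevation, 160)", "climate_zone",
    "population_density", "agri_proportion", "hinge(agri_proportion, 0.09)"
  ))
}

#' @rdname bite_model_spec
#' @export
envenoming_model_spec <- function() {
  model_spec("envenoming", c(
    "elevation", "hinge(elevation, 195)", "climate_zone",
    "population_density"
  ))
}

response_column <- function(spec) {
  switch(spec$response, bites = "y_bites", envenoming = "y_envenoming")
}

spec_formula <- function(spec, with_response = TRUE) {
  rhs <- paste(spec$terms, collapse = " + ")
  lhs <- if (with_response) response_column(spec) else ""
  stats::as.formula(paste(lhs, "~", rhs), env = asNamespace("snakerisk"))
}

#' Design matrix for a model specification
#'
#' Evaluates the spec's terms on a cluster table or prediction grid and
#' returns the model matrix (with intercept). Climate zone is coerced to a
#' factor with levels dry < intermediate < wet so the dummy coding is stable
#' whatever subset of zones a data set contains.
#'
#' @param spec a [model_spec()].
#' @param data data.frame with every covariate the spec names.
#' @return numeric matrix, one row per row of `data`.
#' @export
build_design <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  if ("climate_zone" %in% names(data)) {
    data$climate_zone <- factor(as.character(data$climate_zone),
                                levels = climate_levels)
    if (anyNA(data$climate_zone)) stopf("unknown climate_zone value")
  }
  mf <- stats::model.frame(spec_formula(spec, with_response = FALSE), data,
                           na.action = stats::na.fail)
  stats::model.matrix(attr(mf, "terms"), mf)
}

#' Fit the exploratory Poisson regression
#'
#' Poisson log-link GLM of cluster counts with offset `log(n_sampled)`,
#' fitted by iteratively reweighted least squares (via [stats::glm()]). This
#' is the non-spatial limit of the geostatistical model and supplies
#' starting values and residual diagnostics for it.
#'
#' @param clusters cluster table (see [read_clusters()] for the schema).
#' @param spec a [model_spec()].
#' @return object of class `snake_glm`: the `glm` fit plus the spec.
#' @export
fit_glm <- function(clusters, spec) {
  stopifnot(inherits(spec, "model_spec"))
  ycol <- response_column(spec)
  if (!ycol %in% names(clusters)) stopf("missing response column `%s`", ycol)
  if (any(clusters$n_sampled <= 0)) stopf("all n_sampled must be > 0")
  X <- build_design(spec, clusters)
  # structurally empty columns (e.g. a hinge with its knot at the data
  # maximum, or a zone dummy for an absent zone) carry no information: they
  # are aliased out, so the fit equals the model without them
  aliased <- colSums(abs(X)) == 0
  Xf <- X[, !aliased, drop = FALSE]
  if (qr(Xf)$rank < ncol(Xf)) stopf("design matrix is rank deficient")
  y <- clusters[[ycol]]
  fit <- stats::glm.fit(Xf, y, family = stats::poisson(),
                        offset = log(clusters$n_sampled))
  if (!fit$converged) stopf("IRLS did not converge")
  # observed-information covariance: solve(X' diag(mu) X)
  V <- chol2inv(chol(crossprod(Xf * sqrt(fit$weights), Xf)))
  dimnames(V) <- list(colnames(Xf), colnames(Xf))
  structure(list(glm = fit, spec = spec,
                 coefficients = stats::setNames(fit$coefficients,
                                                colnames(Xf)),
                 vcov = V,
                 aliased = names(which(aliased)),
                 deviance = fit$deviance),
            class = "snake_glm")
}

#' @export
print.snake_glm <- function(x, ...) {
  cat("Poisson GLM (offset log n_sampled), response:", x$spec$response, "\n")
  print(coef_table(x))
  cat("Deviance:", format(x$deviance), "on", x$glm$df.residual, "df\n")
  if (length(x$aliased)) {
    cat("Aliased (all-zero) terms:", paste(x$aliased, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Coefficient table in the published layout
#'
#' @param fit a `snake_glm` or `mcml_fit`.
#' @return data.frame with columns `variable`, `estimate`, `std_error`,
#'   `z_value`, `p_value`.
#' @export
coef_table <- function(fit) {
  if (inherits(fit, "snake_glm")) {
    est <- fit$coefficients
    se <- sqrt(diag(fit$vcov))
  } else {
    est <- fit$params$beta
    se <- if (is.null(fit$std_errors)) rep(NA_real_, length(est))
          else fit$std_errors[seq_along(est)]
  }
  z <- est / se
  data.frame(variable = names(est), estimate = unname(est),
             std_error = unname(se), z_value = unname(z),
             p_value = unname(2 * stats::pnorm(-abs(z))),
             row.names = NULL)
}

#' Select a hinge breakpoint by a deviance scan
#'
#' Replaces the hinge knot for `variable` in `spec` (adding a hinge term if
#' the spec has none) by each candidate in turn, fits the Poisson GLM, and
#' returns the candidate with the smallest deviance together with the full
#' deviance profile. A transparent stand-in for smooth-curve (GAM)
#' exploration: the downstream geostatistical model only needs the knot.
#'
#' @param clusters cluster table.
#' @param spec a [model_spec()] containing a linear term for `variable`.
#' @param variable covariate name to scan.
#' @param candidate_knots numeric vector (>= 1) of candidate knots; must lie
#'   inside the observed range of the variable.
#' @return list of class `piecewise_spec`: `variable`, `knot`, `profile`
#'   (data.frame knot/deviance), `at_boundary` (TRUE when the optimum is an
#'   endpoint of the grid, i.e. no interior slope change is supported), and
#'   `spec` updated with the selected knot.
#' @export
select_breakpoint <- function(clusters, spec, variable, candidate_knots) {
  stopifnot(inherits(spec, "model_spec"))
  if (!variable %in% names(clusters)) stopf("unknown variable `%s`", variable)
  rng <- range(clusters[[variable]])
  if (any(candidate_knots < rng[1] | candidate_knots > rng[2])) {
    stopf("candidate knots outside the observed range of `%s`", variable)
  }
  candidate_knots <- sort(unique(candidate_knots))
  hinge_pat <- sprintf("^hinge\\(%s,", variable)
  base_terms <- spec$terms[!grepl(hinge_pat, spec$terms)]
  dev <- vapply(candidate_knots, function(k) {
    sp <- model_spec(spec$response,
                     append(base_terms, sprintf("hinge(%s, %.10g)", variable, k)))
    fit <- tryCatch(fit_glm(clusters, sp), error = function(e) NULL)
    if (is.null(fit)) NA_real_ else fit$deviance
  }, numeric(1))
  if (all(is.na(dev))) stopf("no candidate knot yielded a valid fit")
  best <- which.min(dev)
  knot <- candidate_knots[best]
  structure(list(
    variable = variable, knot = knot,
    profile = data.frame(knot = candidate_knots, deviance = dev),
    at_boundary = best %in% c(1L, length(candidate_knots)),
    spec = model_spec(spec$response,
                      append(base_terms,
                             sprintf("hinge(%s, %.10g)", variable, knot)))
  ), class = "piecewise_spec")
}

#' Pearson residuals at cluster locations
#'
#' `(y - mu) / sqrt(mu)` per cluster, attached to the cluster coordinates so
#' they can be mapped and fed to [empirical_variogram()]. Clusters with
#' fitted mean zero get `NA` and are flagged.
#'
#' @param clusters cluster table used in the fit.
#' @param fit a `snake_glm`.
#' @return data.frame `x_km`, `y_km`, `residual`, `undefined`.
#' @export
standardized_residuals <- function(clusters, fit) {
  stopifnot(inherits(fit, "snake_glm"))
  mu <- fit$glm$fitted.values
  y <- clusters[[response_column(fit$spec)]]
  undef <- mu == 0
  r <- ifelse(undef, NA_real_, (y - mu) / sqrt(mu))
  data.frame(x_km = clusters$x_km, y_km = clusters$y_km,
             residual = r, undefined = undef)
}
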