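# Published summary figures from the 2012-13 national community-based
# snakebite survey of Sri Lanka (1118 GN-division clusters, 165665 people,
# ~0.8% of the population). These printed tables are the reference inputs
# for worked examples and consistency checks: the underlying microdata are
# not redistributed here.

#' Province-level snakebite and envenoming incidence
#'
#' Reported sample counts, population-extrapolated counts and design-based
#' incidence rates (per 100 000 person-years, 95% CI) for the nine provinces
#' of Sri Lanka, plus the national totals, as published from the 2012-13
#' national snakebite survey.
#'
#' @return data.frame, one row per province plus a `"National"` row, with
#'   columns `province`, `climate_zone`, `bites_reported`, `bites_estimated`,
#'   `bites_rate`, `bites_ci_low`, `bites_ci_high`, and the same six fields
#'   for envenoming (`env_*`).
#' @examples
#' tab <- province_incidence_table()
#' sum(tab$bites_estimated[tab$province != "National"])  # 80514
#' @export
province_incidence_table <- function() {
  tab <- data.frame(
    province = c("Western", "Central", "Sabaragamuwa", "Northwestern",
                 "Southern", "Uva", "Northern", "Eastern", "Northcentral",
                 "National"),
    climate_zone = c("wet", "wet", "wet", "wet/intermediate",
                     "wet/intermediate", "dry/intermediate", "dry", "dry",
                     "dry", NA),
    bites_reported = c(61, 45, 102, 92, 87, 63, 59, 67, 119, 695),
    bites_estimated = c(18910, 7065, 10506, 11776, 11310, 4095, 3422, 5695,
                        7735, 80514),
    bites_rate = c(325, 277, 548, 499, 461, 328, 324, 368, 623, 398),
    bites_ci_low = c(217, 182, 438, 392, 338, 242, 219, 227, 487, 356),
    bites_ci_high = c(432, 371, 658, 605, 584, 414, 428, 509, 760, 441),
    env_reported = c(12, 15, 35, 34, 18, 39, 42, 44, 84, 323),
    env_estimated = c(3720, 2355, 3605, 4352, 2340, 2535, 2436, 3740, 5460,
                      30543),
    env_rate = c(64, 92, 188, 184, 95, 203, 230, 242, 440, 151),
    env_ci_low = c(27, 42, 127, 118, 47, 137, 145, 119, 325, 130),
    env_ci_high = c(101, 142, 249, 251, 144, 270, 316, 365, 555, 173)
  )
  tab
}

#' Published incidence by sex
#'
#' Sample counts and incidence rates (per 100 000, 95% CI) of snakebite and
#' envenoming for males and females from the national survey.
#'
#' @return data.frame with one row per sex.
#' @export
sex_incidence_table <- function() {
  data.frame(
    sex = c("male", "female"),
    bites_reported = c(418, 277),
    env_reported = c(193, 130),
    bites_rate = c(478, 320),
    bites_ci_low = c(414, 273),
    bites_ci_high = c(541, 367),
    env_rate = c(176, 126),
    env_ci_low = c(146, 100),
    env_ci_high = c(207, 154)
  )
}

#' Published clinical features of snakebite victims
#'
#' Counts and printed percentages of clinical features recalled by the 695
#' snakebite victims in the national survey sample.
#'
#' @return data.frame with columns `feature`, `count`, `percent` and the
#'   denominator as attribute `n_victims`.
#' @export
clinical_features_table <- function() {
  out <- data.frame(
    feature = c("swelling", "neurological", "abdominal_pain",
                "tissue_necrosis", "bleeding", "renal_impairment"),
    count = c(606, 197, 169, 110, 104, 33),
    percent = c(87.2, 28.3, 24.3, 15.8, 15.0, 4.8)
  )
  attr(out, "n_victims") <- 695L
  out
}

#' Published geostatistical parameter estimates
#'
#' Coefficients (log incidence scale, per person-year) and covariance
#' parameters of the fitted geostatistical Poisson models for snakebite and
#' for envenoming, as published from the national survey. These are the
#' default "true" parameters of the synthetic-data generator, so simulated
#' worlds live on the same scale as the published fit. Elevation is in
#' metres, population density in persons per square km, the share of
#' agricultural workers is a proportion in [0, 1] (the published breakpoint
#' "9%" is 0.09 on this scale), and climate-zone effects are relative to the
#' dry zone. `phi` is interpreted in kilometres (the declared distance unit
#' of this package).
#'
#' @param response `"bites"` or `"envenoming"`.
#' @return list with `beta` (named vector), `se` (named vector, coefficient
#'   standard errors), `sigma2`, `phi`, `tau2`, `kappa` (fixed at 0.5) and
#'   the matching [model_spec()].
#' @examples
#' p <- published_geostat_params("bites")
#' exp(sum(p$beta * c(1, 160, 0, 0, 1, 0, 0.09, 0))) * 1e5  # ~742 per 100 000
#' @export
published_geostat_params <- function(response = c("bites", "envenoming")) {
  response <- match.arg(response)
  if (response == "bites") {
    beta <- c(
      "(Intercept)" = -6.6239,
      "elevation" = 0.0032,
      "hinge(elevation, 160)" = -0.0046,
      "climate_zoneintermediate" = 0.2225,
      "climate_zonewet" = 0.5586,
      "population_density" = -0.0002,
      "agri_proportion" = 7.2235,
      "hinge(agri_proportion, 0.09)" = -6.4166
    )
    se <- c(0.13456, 0.00079, 0.00085, 0.10564, 0.11763, 0.00002, 1.3366,
            1.4017)
    cov <- list(sigma2 = 0.189, phi = 0.091, tau2 = 0.304)
    spec <- bite_model_spec()
  } else {
    beta <- c(
      "(Intercept)" = -6.0911,
      "elevation" = 0.0043,
      "hinge(elevation, 195)" = -0.0046,
      "climate_zoneintermediate" = -0.4781,
      "climate_zonewet" = -0.8093,
      "population_density" = -0.0005
    )
    se <- c(0.055, 0.00049, 0.00053, 0.07657, 0.08098, 0.00002)
    cov <- list(sigma2 = 0.055475, phi = 0.129351, tau2 = 0.247201)
    spec <- envenoming_model_spec()
  }
  names(se) <- names(beta)
  c(list(beta = beta, se = se), cov, list(kappa = 0.5, spec = spec))
}
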