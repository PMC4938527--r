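# Design-based incidence estimation for a stratified two-stage cluster
# sample. Rates are ratio estimates (events per person sampled) with Taylor
# linearization variances treating first-stage clusters as drawn with
# replacement; national figures combine strata by population weight.

#' Survey design: strata and their population totals
#'
#' @param strata data.frame with columns `stratum` and `population`
#'   (persons; > 0).
#' @return object of class `survey_design`.
#' @export
survey_design <- function(strata) {
  need <- c("stratum", "population")
  if (!all(need %in% names(strata))) stopf("strata needs columns %s",
                                           paste(need, collapse = ", "))
  if (anyDuplicated(strata$stratum)) stopf("duplicated stratum ids")
  if (any(!is.finite(strata$population)) || any(strata$population <= 0)) {
    stopf("population totals must be positive")
  }
  structure(list(strata = strata[, need]), class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat("Survey design:", nrow(x$strata), "strata, total population",
      format(sum(x$strata$population), big.mark = ","), "\n")
  invisible(x)
}

new_rate_estimate <- function(rate, se, n_events, n_persons,
                              population = NA_real_) {
  ci <- if (is.na(se)) c(NA_real_, NA_real_) else {
    rate + c(-1, 1) * stats::qnorm(0.975) * se
  }
  ci[1] <- max(0, ci[1])
  count <- if (is.na(population)) NA_real_ else {
    round_half_up(rate / 1e5 * population)
  }
  structure(list(rate = rate, se = se, ci_low = ci[1], ci_high = ci[2],
                 n_events = n_events, n_persons = n_persons,
                 population = population, estimated_count = count,
                 ci_available = !is.na(se)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%.1f per 100 000 (95%% CI %.1f-%.1f); %d events / %d persons\n",
              x$rate, x$ci_low, x$ci_high, x$n_events, x$n_persons))
  if (!is.na(x$estimated_count)) {
    cat(sprintf("  extrapolated: %d events in population %s\n",
                as.integer(x$estimated_count),
                format(x$population, big.mark = ",")))
  }
  invisible(x)
}

# Core ratio estimator on event/person vectors for the clusters of one
# stratum. With R = sum(y)/sum(n) and z_i = y_i - R n_i, the linearized
# with-replacement variance is  m/(m-1) * sum(z_i^2) / (sum n_i)^2.
ratio_rate <- function(y, n, population = NA_real_) {
  if (length(y) != length(n) || length(y) < 1L) stopf("y and n must match")
  if (any(n <= 0)) stopf("all cluster denominators must be > 0")
  if (any(y < 0)) stopf("negative counts")
  m <- length(y)
  R <- sum(y) / sum(n)
  se <- if (m >= 2) {
    z <- y - R * n
    1e5 * sqrt(m / (m - 1) * sum(z^2)) / sum(n)
  } else NA_real_
  new_rate_estimate(1e5 * R, se, sum(y), sum(n), population)
}

#' Design-based incidence rate for one stratum
#'
#' Pooled ratio estimate `1e5 * sum(y) / sum(n)` over the stratum's
#' clusters, with Taylor-linearization variance treating first-stage
#' clusters as sampled with replacement (no finite-population correction;
#' sampling fractions in surveys of this design are ~1%). The 95% CI is
#' normal-based and truncated at zero. With a single cluster the rate is
#' returned with the CI flagged unavailable.
#'
#' @param clusters cluster table for one stratum (columns `y_bites` /
#'   `y_envenoming` and `n_sampled`).
#' @param response `"bites"` or `"envenoming"`.
#' @param population stratum population total for extrapolation (optional).
#' @return object of class `rate_estimate` with fields `rate`, `se`,
#'   `ci_low`, `ci_high`, `n_events`, `n_persons`, `estimated_count`.
#' @examples
#' cl <- data.frame(y_bites = c(2, 3, 5), n_sampled = c(1000, 1000, 1000))
#' stratum_rate(cl)$rate  # 333.33 per 100 000
#' @export
stratum_rate <- function(clusters, response = "bites",
                         population = NA_real_) {
  ycol <- if (response == "bites") "y_bites" else "y_envenoming"
  ratio_rate(clusters[[ycol]], clusters$n_sampled, population)
}

#' National rate from per-stratum estimates
#'
#' Population-weighted combination of stratum rates with variance
#' `sum(W_h^2 var_h)`, `W_h` the stratum population shares. This is the
#' standard stratified estimator: strata contribute independent sampling
#' errors.
#'
#' @param estimates named list of `rate_estimate`, one per design stratum
#'   (names = stratum ids).
#' @param design a [survey_design()].
#' @return a `rate_estimate` for the whole population.
#' @export
national_rate <- function(estimates, design) {
  stopifnot(inherits(design, "survey_design"))
  ids <- design$strata$stratum
  if (!all(ids %in% names(estimates))) {
    stopf("missing estimate for stratum %s",
          paste(setdiff(ids, names(estimates)), collapse = ", "))
  }
  estimates <- estimates[ids]
  W <- design$strata$population / sum(design$strata$population)
  rates <- vapply(estimates, `[[`, numeric(1), "rate")
  ses <- vapply(estimates, `[[`, numeric(1), "se")
  rate <- sum(W * rates)
  se <- if (anyNA(ses)) NA_real_ else sqrt(sum(W^2 * ses^2))
  new_rate_estimate(rate, se,
                    sum(vapply(estimates, `[[`, numeric(1), "n_events")),
                    sum(vapply(estimates, `[[`, numeric(1), "n_persons")),
                    sum(design$strata$population))
}

#' Extrapolate a rate to a population count
#'
#' `count = rate / 100000 * population`, with CI endpoints scaled the same
#' way; all three rounded half-up to whole events.
#'
#' @param estimate a `rate_estimate`.
#' @param population persons (> 0).
#' @return list `count`, `ci_low`, `ci_high`.
#' @export
extrapolate_count <- function(estimate, population) {
  assert_scalar_num(population, "population", 0, strict_lower = TRUE)
  f <- function(r) if (is.na(r)) NA_real_ else round_half_up(r / 1e5 * population)
  list(count = f(estimate$rate), ci_low = f(estimate$ci_low),
       ci_high = f(estimate$ci_high))
}

#' Province-by-province incidence table
#'
#' Applies [stratum_rate()] within each design stratum and [national_rate()]
#' across them, for one response, producing a table shaped like published
#' province incidence summaries.
#'
#' @param clusters cluster table with a `stratum` column.
#' @param design a [survey_design()].
#' @param response `"bites"` or `"envenoming"`.
#' @return data.frame, one row per stratum plus a `"National"` row, with
#'   columns `stratum`, `population`, `reported`, `estimated`, `rate`,
#'   `ci_low`, `ci_high`.
#' @export
incidence_by_stratum <- function(clusters, design, response = "bites") {
  stopifnot(inherits(design, "survey_design"))
  ids <- design$strata$stratum
  if (!all(clusters$stratum %in% ids)) {
    stopf("clusters reference strata absent from the design")
  }
  ests <- lapply(seq_along(ids), function(h) {
    stratum_rate(clusters[clusters$stratum == ids[h], , drop = FALSE],
                 response, design$strata$population[h])
  })
  names(ests) <- ids
  nat <- national_rate(ests, design)
  row <- function(id, pop, e) {
    data.frame(stratum = id, population = pop, reported = e$n_events,
               estimated = e$estimated_count, rate = e$rate,
               ci_low = e$ci_low, ci_high = e$ci_high)
  }
  out <- do.call(rbind, c(
    lapply(seq_along(ids),
           function(h) row(ids[h], design$strata$population[h], ests[[h]])),
    list(row("National", sum(design$strata$population), nat))
  ))
  rownames(out) <- NULL
  out
}
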