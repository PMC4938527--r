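# End-to-end driver: simulate (optional) -> survey -> explore -> fit ->
# predict -> map, writing every intermediate artifact plus a manifest that
# records seeds, package version, per-stage wall time and a config
# fingerprint. Any stage failure halts with the stage name; artifacts from
# completed stages are left in place.

#' Run the full analysis pipeline
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the artifact directory. Files written: `clusters.csv`,
#'   `strata.csv`, `grid.csv` (simulate), `incidence_by_stratum.csv`
#'   (survey), `glm_coefficients.csv` and `residual_variogram.csv`
#'   (explore), `mcml_fit.json` and `mcml_coefficients.csv` (fit),
#'   `surface.csv` (predict), `exceedance_maps.csv` and
#'   `exceedance_summary.csv` (map), and `manifest.json`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "snakerisk",
                   version = as.character(utils::packageVersion("snakerisk")),
                   seed = config$seed,
                   config_hash = fnv1a(jsonlite::toJSON(
                     config[setdiff(names(config), "mcmc")],
                     auto_unbox = TRUE, force = TRUE)),
                   stages = list())
  t_all <- Sys.time()
  stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      stopf("pipeline stage `%s` failed: %s", name, conditionMessage(e))
    })
    manifest$stages[[name]] <<- list(
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3))
    message(sprintf("[%s] done in %.1fs", name,
                    manifest$stages[[name]]$seconds))
    res
  }
  pth <- function(f) file.path(config$outdir, f)

  world <- stage("simulate", function() {
    if (config$simulate) {
      w <- simulate_survey(
        seed = config$seed, n_strata = config$n_strata,
        clusters_per_stratum = config$clusters_per_stratum,
        persons_per_cluster_mean = config$persons_per_cluster_mean,
        extent_km = config$extent_km, resolution_km = config$resolution_km)
      write_clusters(w$clusters, pth("clusters.csv"))
      utils::write.csv(w$design$strata, pth("strata.csv"), row.names = FALSE)
      write_grid(w$grid, pth("grid.csv"))
      w
    } else {
      list(clusters = read_clusters(config$clusters_path),
           design = read_strata(config$strata_path),
           grid = read_grid(config$grid_path))
    }
  })
  clusters <- world$clusters
  design <- world$design

  spec <- if (config$response == "bites") bite_model_spec()
          else envenoming_model_spec()

  stage("survey", function() {
    tab <- incidence_by_stratum(clusters, design, config$response)
    utils::write.csv(tab, pth("incidence_by_stratum.csv"), row.names = FALSE)
    tab
  })

  glm_fit <- stage("explore", function() {
    fit <- fit_glm(clusters, spec)
    utils::write.csv(coef_table(fit), pth("glm_coefficients.csv"),
                     row.names = FALSE)
    res <- standardized_residuals(clusters, fit)
    span <- max(stats::dist(clusters[, c("x_km", "y_km")]))
    vg <- empirical_variogram(res$residual[!res$undefined],
                              res[!res$undefined, c("x_km", "y_km")],
                              seq(0, span / 2, length.out = 11))
    utils::write.csv(vg, pth("residual_variogram.csv"), row.names = FALSE)
    fit
  })

  fit <- stage("fit", function() {
    f <- fit_mcml(clusters, spec,
                  init = list(beta = glm_fit$coefficients, sigma2 = 0.15,
                              phi = config$resolution_km, tau2 = 0.15),
                  control = config$mcmc, seed = config$seed)
    utils::write.csv(coef_table(f), pth("mcml_coefficients.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(beta = as.list(f$params$beta), sigma2 = f$params$sigma2,
           phi = f$params$phi, tau2 = f$params$tau2,
           converged = f$converged, loglik_ratio = f$loglik_ratio,
           acceptance = f$diagnostics$acceptance, ess = f$diagnostics$ess),
      pth("mcml_fit.json"), auto_unbox = TRUE, digits = NA)
    f
  })

  pred_grid <- world$grid
  if (config$grid_resolution_km != config$resolution_km &&
      config$simulate) {
    pred_grid <- make_domain(config$extent_km, config$grid_resolution_km,
                             seed = config$seed)
  }

  draws <- stage("predict", function() {
    d <- krige_conditional(fit, clusters, pred_grid,
                           seed = split_seed(config$seed, "predict"))
    surf <- incidence_surface(fit, pred_grid, d)
    utils::write.csv(surf, pth("surface.csv"), row.names = FALSE)
    d
  })

  stage("map", function() {
    em <- threshold_suite(fit, pred_grid, draws, config$thresholds)
    utils::write.csv(em$maps, pth("exceedance_maps.csv"), row.names = FALSE)
    utils::write.csv(em$summary, pth("exceedance_summary.csv"),
                     row.names = FALSE)
    em
  })

  manifest$total_seconds <- round(as.numeric(
    difftime(Sys.time(), t_all, units = "secs")), 3)
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(config$outdir)
}
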