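# File formats and validation. Everything is plain CSV (comma separated,
# period decimal, header required) or JSON/YAML for configuration, so every
# artifact the pipeline writes is re-readable by these functions.

cluster_required_cols <- c("cluster_id", "n_sampled", "y_bites",
                           "y_envenoming", "elevation", "population_density",
                           "agri_proportion", "climate_zone", "stratum")

#' Read and validate a cluster table
#'
#' Expects a header CSV with one row per survey cluster. Coordinates are
#' either planar (`x_km`, `y_km`) or geographic (`lon`, `lat`, decimal
#' degrees); geographic coordinates are projected to km internally (see
#' [lonlat_to_km()]). Remaining columns: `cluster_id`, `n_sampled`,
#' `y_bites`, `y_envenoming`, `elevation`, `population_density`,
#' `agri_proportion`, `climate_zone` (dry/intermediate/wet), `stratum`.
#' Columns named differently can be declared via `mapping`
#' (e.g. `mapping = c(y_bites = "bite_count")`).
#'
#' Validation failures report the offending row and field.
#'
#' @param path CSV file path.
#' @param mapping optional named character vector, `standard = actual`.
#' @return validated data.frame of cluster records with `x_km`, `y_km`.
#' @export
read_clusters <- function(path, mapping = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stopf("no records in %s", path)
  if (!is.null(mapping)) {
    for (std in names(mapping)) {
      if (!mapping[[std]] %in% names(df)) {
        stopf("mapped column `%s` not found", mapping[[std]])
      }
      names(df)[names(df) == mapping[[std]]] <- std
    }
  }
  validate_clusters(df, origin = path)
}

#' Validate a cluster table already in memory
#'
#' @param df data.frame of cluster records.
#' @param origin label used in error messages.
#' @return the validated (possibly projected) data.frame.
#' @export
validate_clusters <- function(df, origin = "clusters") {
  if (all(c("lon", "lat") %in% names(df)) &&
      !all(c("x_km", "y_km") %in% names(df))) {
    xy <- lonlat_to_km(df$lon, df$lat)
    df$x_km <- xy$x_km
    df$y_km <- xy$y_km
  }
  missing <- setdiff(c(cluster_required_cols, "x_km", "y_km"), names(df))
  if (length(missing)) {
    stopf("%s: missing column(s) %s", origin, paste(missing, collapse = ", "))
  }
  num_cols <- c("x_km", "y_km", "n_sampled", "y_bites", "y_envenoming",
                "elevation", "population_density", "agri_proportion")
  for (col in num_cols) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad)) stopf("%s: row %d, field `%s`: unparsable or non-finite",
                           origin, bad[1], col)
    df[[col]] <- as.numeric(df[[col]])
  }
  check <- function(cond, field) {
    bad <- which(!cond)
    if (length(bad)) stopf("%s: row %d, field `%s`: invariant violated",
                           origin, bad[1], field)
  }
  check(df$n_sampled > 0, "n_sampled")
  check(df$y_bites >= 0, "y_bites")
  check(df$y_envenoming >= 0, "y_envenoming")
  check(df$y_envenoming <= df$y_bites, "y_envenoming <= y_bites")
  check(df$agri_proportion >= 0 & df$agri_proportion <= 1, "agri_proportion")
  check(as.character(df$climate_zone) %in% climate_levels, "climate_zone")
  df$climate_zone <- factor(as.character(df$climate_zone),
                            levels = climate_levels)
  df
}

#' Write a cluster table
#' @param clusters validated cluster table.
#' @param path output CSV path.
#' @export
write_clusters <- function(clusters, path) {
  utils::write.csv(clusters, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a covariate grid
#'
#' Grid CSVs carry `x_km`, `y_km` and the covariate columns.
#' @param path CSV path.
#' @return `covariate_grid` data.frame.
#' @export
read_grid <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_km", "y_km", "elevation", "population_density",
            "agri_proportion", "climate_zone")
  missing <- setdiff(need, names(df))
  if (length(missing)) stopf("%s: missing column(s) %s", path,
                             paste(missing, collapse = ", "))
  df$climate_zone <- factor(as.character(df$climate_zone),
                            levels = climate_levels)
  structure(df, class = c("covariate_grid", "data.frame"))
}

#' @rdname read_grid
#' @param grid a covariate grid.
#' @export
write_grid <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read stratum population totals
#' @param path CSV with columns `stratum`, `population`.
#' @return a [survey_design()].
#' @export
read_strata <- function(path) {
  survey_design(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Pipeline configuration
#'
#' Assembles and validates the settings the end-to-end pipeline needs. All
#' arguments have working defaults, so `pipeline_config(outdir = d)` runs
#' the full synthetic demonstration.
#'
#' @param outdir artifact directory (created if needed).
#' @param seed master seed; every stage derives its own stream from it.
#' @param simulate generate synthetic inputs (TRUE) or read them from
#'   `clusters_path` / `strata_path` / `grid_path`.
#' @param clusters_path,strata_path,grid_path input files when
#'   `simulate = FALSE`.
#' @param response `"bites"` or `"envenoming"`.
#' @param thresholds exceedance thresholds per 100 000.
#' @param n_strata,clusters_per_stratum,persons_per_cluster_mean,extent_km,resolution_km
#'   synthetic-design knobs (see [simulate_survey()] / [make_domain()]).
#' @param grid_resolution_km prediction grid spacing.
#' @param mcmc an [mcml_control()].
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1, simulate = TRUE,
                            clusters_path = NULL, strata_path = NULL,
                            grid_path = NULL, response = "bites",
                            thresholds = c(300, 398, 500),
                            n_strata = 9, clusters_per_stratum = 25,
                            persons_per_cluster_mean = 148,
                            extent_km = c(240, 400), resolution_km = 20,
                            grid_resolution_km = 20,
                            mcmc = mcml_control(burnin = 500, thin = 4,
                                                n_draws = 300,
                                                max_anchors = 3)) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  validate_config(cfg)
}

#' Validate a pipeline configuration
#' @param cfg a list shaped like [pipeline_config()] output.
#' @return the config, invisibly classed, or an error naming the bad field.
#' @export
validate_config <- function(cfg) {
  if (is.null(cfg$outdir) || !is.character(cfg$outdir)) {
    stopf("config: `outdir` is required")
  }
  assert_scalar_num(cfg$seed, "seed")
  if (!cfg$response %in% c("bites", "envenoming")) {
    stopf("config: response must be 'bites' or 'envenoming'")
  }
  if (any(!is.finite(cfg$thresholds)) || any(cfg$thresholds < 0)) {
    stopf("config: thresholds must be non-negative numbers")
  }
  if (!isTRUE(cfg$simulate)) {
    for (f in c("clusters_path", "strata_path", "grid_path")) {
      if (is.null(cfg[[f]]) || !file.exists(cfg[[f]])) {
        stopf("config: `%s` must point to an existing file", f)
      }
    }
  }
  if (!inherits(cfg$mcmc, "mcml_control")) {
    cfg$mcmc <- do.call(mcml_control, cfg$mcmc)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from JSON or YAML
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @return validated `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stopf("the yaml package is needed for YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  defaults <- formals(pipeline_config)
  known <- names(defaults)
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stopf("config: unknown field(s) %s",
                             paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}
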