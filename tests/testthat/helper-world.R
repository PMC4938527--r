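# Shared fixtures, built in code. One small synthetic world and one MCML fit
# are memoised per test run so several test files can reuse them.

.shared <- new.env(parent = emptyenv())

small_world <- function() {
  if (is.null(.shared$world)) {
    .shared$world <- simulate_survey(seed = 9, clusters_per_stratum = 20,
                                     resolution_km = 20)
  }
  .shared$world
}

small_fit <- function() {
  if (is.null(.shared$fit)) {
    w <- small_world()
    .shared$fit <- suppressWarnings(fit_mcml(
      w$clusters, bite_model_spec(),
      control = mcml_control(burnin = 300, thin = 2, n_draws = 300,
                             max_anchors = 3),
      seed = 2))
  }
  .shared$fit
}

# clusters with no spatial structure simulated from known coefficients
nonspatial_clusters <- function(n = 400, beta, spec, n_sampled = 2000,
                                seed = 5) {
  g <- make_domain(c(200, 200), 10, seed = seed)
  cl <- as.data.frame(g)[sample_int(nrow(g), n, seed), , drop = FALSE]
  cl$n_sampled <- n_sampled
  cl$stratum <- "P01"
  cl$cluster_id <- sprintf("C%04d", seq_len(n))
  tm <- true_model(beta = beta, sigma2 = 0, phi = 1, tau2 = 0, spec = spec)
  simulate_counts(cl, tm, seed = seed + 1)
}

sample_int <- function(n, k, seed) {
  set.seed(seed)
  sample.int(n, k, replace = TRUE)
}

with_seed_test <- function(seed, expr) {
  set.seed(seed)
  expr
}
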