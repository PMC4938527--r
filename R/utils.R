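# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so package functions never clobber user seeds.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a stage-specific seed from one master seed, so
# pipeline stages (domain / clusters / field / counts / mcmc) can be rerun
# independently. Kept below 2^31 - 1.
split_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage)) %% 1000L
  as.integer((abs(as.numeric(seed)) * 1009 + h * 31 + 17) %% 2147483647)
}

# Round half away from zero, as printed summary tables do (round() in R
# rounds half to even).
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  if (strict_lower && x <= lower) stopf("`%s` must be > %g", name, lower)
  if (!strict_lower && x < lower) stopf("`%s` must be >= %g", name, lower)
  if (x > upper) stopf("`%s` must be <= %g", name, upper)
  invisible(x)
}

# Euclidean distance matrix between two coordinate sets (n x 2, m x 2), km.
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Tiny FNV-1a hash of a character scalar; used for config fingerprints in
# pipeline manifests (no external digest dependency).
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
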