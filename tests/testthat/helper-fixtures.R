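# Shared fixtures, built in code at test time.

# Null world: no group effects, no zero inflation, no planted correlations.
null_config <- function(seed = 1, noise_cv = 0.2, ...) {
  generator_config(seed = seed, site_effect_scale = 0,
                   collection_effect_scale = 0,
                   cooking_effects = NULL, production_effects = NULL,
                   noise_cv = noise_cv, zero_inflation = c(As = 0),
                   correlation_partners = list(), ...)
}

# Strongly separated world: between-group log-sd five times the biological
# within-group scatter, with distinct collection batches.
strong_config <- function(seed = 1) {
  generator_config(seed = seed, site_effect_scale = 1,
                   collection_effect_scale = 0.5)
}

# Small profile table from bare matrices, for unit tests of the filters and
# models that do not need the full generator.
profile_from_matrix <- function(x, group = NULL, preparation = NULL) {
  n <- nrow(x)
  out <- data.frame(sample_id = sprintf("T%03d", seq_len(n)),
                    group = if (is.null(group)) rep("g1", n) else group,
                    stringsAsFactors = FALSE)
  if (!is.null(preparation)) out$preparation <- preparation
  for (el in colnames(x)) {
    out[[paste0(el, "_ppm")]] <- x[, el]
    out[[paste0(el, "_err")]] <- abs(x[, el]) * 0.05
  }
  class(out) <- c("sep_profile", "data.frame")
  out
}

# Fixture for the correlation filter: Ca is a near-copy of K (plus a little
# P), Fe a near-copy of S (plus a little Cl), everything else independent.
correlated_fixture <- function(seed = 42, n = 40) {
  set.seed(seed)
  base <- matrix(rnorm(n * 5), n,
                 dimnames = list(NULL, c("P", "S", "Cl", "K", "Zn")))
  x <- cbind(base,
             Ca = base[, "K"] + 0.3 * base[, "P"] + rnorm(n, 0, 0.05),
             Fe = base[, "S"] + 0.3 * base[, "Cl"] + rnorm(n, 0, 0.05))
  profile_from_matrix(x + 10)
}
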