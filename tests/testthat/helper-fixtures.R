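# Shared fixtures, built in code. Heavy objects are created once per test
# run and reused across files.

# a flat-spectrum dataset with an absorption dip, for hull/transform tests
make_dip_ds <- function() {
  w <- 400:900
  r <- 0.5 - 0.3 * exp(-(w - 670)^2 / (2 * 30^2))
  spectral_dataset(w, matrix(r, 1), condition = "S1", chlorophyll = 30)
}

# small campaign reused by several files (12 plants per condition)
tiny_campaign <- generate_campaign(n_per_condition = 12, seed = 7)

# a quick variant config for pipeline mechanics tests (not for accuracy)
fast_config <- function(variant, ...) {
  args <- utils::modifyList(
    list(feature_dim = 32L, n_blocks = 1L, pretrain_epochs = 15L,
         patience = 5L, adapt_epochs = 10L),
    list(...))
  do.call(variant_config, c(list(variant), args))
}

# brute-force upper-hull continuum: the concave envelope of a point set is
# the pointwise minimum, over all chords that dominate every point, of the
# chord's value (endpoint chords included)
brute_force_continuum <- function(x, y) {
  n <- length(x)
  env <- rep(Inf, n)
  for (j in 1:(n - 1)) {
    for (k in (j + 1):n) {
      slope <- (y[k] - y[j]) / (x[k] - x[j])
      line <- y[j] + slope * (x - x[j])
      if (all(line >= y - 1e-12)) env <- pmin(env, line)
    }
  }
  env
}
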