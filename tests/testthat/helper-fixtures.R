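# Shared fixtures, generated once per test run and cached in-session.

.fixtures <- new.env(parent = emptyenv())

.cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

fixture_molecules <- function(n = 100, seed = 7) {
  .cached(sprintf("mols_%d_%d", n, seed),
          generate_molecules(generator_config(n_molecules = n, seed = seed)))
}

fixture_dataset <- function(n = 100, seed = 7, ...) {
  .cached(sprintf("ds_%d_%d_%s", n, seed, paste(deparse(list(...)), collapse = "")), {
    cfg <- generator_config(n_molecules = n, seed = seed, ...)
    assign_labels(generate_molecules(cfg), cfg)
  })
}

# descriptor matrix for cached molecules
fixture_descriptors <- function(n = 100, seed = 7) {
  .cached(sprintf("desc_%d_%d", n, seed), descriptors(fixture_molecules(n, seed)))
}

fixture_fingerprints <- function(n = 100, seed = 7) {
  .cached(sprintf("fp_%d_%d", n, seed),
          fingerprint(fixture_molecules(n, seed), "morgan_bits"))
}

# a clean, learnable single-feature ordinal problem: y = number of
# thresholds that the feature exceeds (no noise)
make_threshold_problem <- function(n = 400, seed = 1) {
  set.seed(seed)
  x <- runif(n, 0, 4)
  y <- findInterval(x, c(1, 2, 3))
  X <- cbind(f = x, junk = rnorm(n))
  list(X = X, y = y)
}
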