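# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

# memoize expensive objects across test files
fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

tiny_atlas <- function(n_roi = 10) {
  make_atlas(n_roi, default_network_sizes(n_roi), seed = 1)
}

# a small but signal-bearing cohort used by several suites
small_cohort <- function() {
  fixture("small_cohort", function() {
    atlas <- make_atlas(20, default_network_sizes(20), seed = 1)
    suppressWarnings(
      simulate_cohort(n_subj = 40, atlas = atlas, n_tr = 120, seed = 404))
  })
}

# deterministic multivariate normal draws for oracle tests
rmvn <- function(n, R) {
  L <- chol(R)
  matrix(stats::rnorm(n * nrow(R)), n) %*% L
}
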