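# Shared fixtures, built once per test run.

fixture_env <- new.env()

small_annotation <- function() {
  if (is.null(fixture_env$ann))
    fixture_env$ann <- simulate_probe_annotation(4000L, 2L, seed = 424L)
  fixture_env$ann
}

small_config <- function(...) sim_config(n_probes = 4000L, n_chrom = 2L, ...)

# a random symmetric zero-diagonal distance matrix
random_dist <- function(k) {
  d <- matrix(0, k, k)
  d[upper.tri(d)] <- stats::runif(k * (k - 1) / 2)
  d + t(d)
}

# exchangeable patient generator: fixed clone distance matrix, uniform
# clone assignment
clone_lookup_draw <- function(D, k) {
  cl <- sample.int(nrow(D), k, replace = TRUE)
  D[cl, cl, drop = FALSE]
}
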