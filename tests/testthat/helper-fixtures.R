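# Shared fixtures: tiny simulated worlds, built once per test run.

four_sample_sheet <- function(lib = 5000L) {
  sheet <- default_sample_sheet()[1:4, ]
  sheet$library_size <- lib
  sheet
}

fe_sample_sheet <- function(lib = 5000L) {
  sheet <- default_sample_sheet()[5:8, ]
  sheet$library_size <- lib
  sheet
}

tiny_config <- function(seed = 1L, samples = four_sample_sheet(), ...) {
  sim_config(seed = seed, n_taxon_groups = 2L, orfs_per_group = 20L,
             orf_length = 300L, samples = samples, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

tiny_bundle <- function() {
  cached("tiny_bundle", simulate_bundle(tiny_config()))
}

# Adjusted Rand index between two partitions (label vectors).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Brute-force NB exact test: normalized dnbinom products over all splits of
# the total; independent of the lgamma route in exact_test_nb().
brute_force_exact_p <- function(a, b, phi, n_a = 1, n_b = 1) {
  t <- a + b
  k <- 0:t
  if (phi <= 0) {
    probs <- stats::dbinom(k, t, n_a / (n_a + n_b))
  } else {
    probs <- stats::dnbinom(k, size = n_a / phi, mu = n_a) *
      stats::dnbinom(t - k, size = n_b / phi, mu = n_b)
    probs <- probs / sum(probs)
  }
  obs <- probs[a + 1]
  min(1, sum(probs[log(probs) <= log(obs) + 1e-10]))
}
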