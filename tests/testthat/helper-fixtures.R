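# Shared fixtures, generated in code and memoized for the test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# the standard acceptance suite (seed fixed)
acceptance_suite <- function() cached("suite0", generate_suite(seed = 0))

# a small two-cell fixture for fast unit tests
small_fx <- function(seed = 11) {
  cached(paste0("small", seed),
         generate_fixture(fixture_spec(seed = seed, size = c(128, 128),
                                       n_cells = 2, radius_range = c(16, 24))))
}

# binary disk mask
disk_mask <- function(nr, nc, cy, cx, r) {
  Y <- matrix(seq_len(nr), nr, nc)
  X <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  matrix(as.integer((X - cx)^2 + (Y - cy)^2 <= r^2), nr, nc)
}

# brute-force Gaussian naive Bayes posterior, written independently of the
# package implementation: plain prior x product of dnorm, normalized
brute_force_posterior <- function(priors, mu, var, X) {
  t(apply(X, 1, function(x) {
    joint <- vapply(seq_along(priors), function(k) {
      priors[k] * prod(stats::dnorm(x, mean = mu[k, ], sd = sqrt(var[k, ])))
    }, numeric(1))
    joint / sum(joint)
  }))
}
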