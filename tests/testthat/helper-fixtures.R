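# Shared fixtures, built in code and memoised across test files.
# Scales are deliberately tiny: unit tests exercise contracts, not
# convergence; the reduced-scale scientific properties live in
# test-acceptance.R.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

tiny_h1 <- function() {
  fixture("tiny_h1", function() {
    generate_dataset(
      synthetic_config("H1", n_train = 80L, n_val = 30L, side = 32L,
                       roi_sizes = c(V1 = 40L, V2 = 30L, V4 = 20L, LO = 10L)),
      seed = 5L)
  })
}

tiny_h0 <- function() {
  fixture("tiny_h0", function() {
    generate_dataset(
      synthetic_config("H0", n_train = 80L, n_val = 30L, side = 32L,
                       roi_sizes = c(V1 = 40L)),
      seed = 7L)
  })
}

fast_config <- function(seed = 3L, ...) {
  train_config(epochs = 20L, boundary = 10L, batch_size = 32L, seed = seed, ...)
}

# independent pointwise Gabor evaluation (the oracle; deliberately loopy and
# separate from the vectorised implementation)
gabor_point_oracle <- function(x, y, theta, lambda, sigma, gamma, psi) {
  xp <- x * cos(theta) + y * sin(theta)
  yp <- -x * sin(theta) + y * cos(theta)
  exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2)) * cos(2 * pi * xp / lambda + psi)
}
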