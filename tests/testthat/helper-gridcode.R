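# shared helpers for the test suite

# small two-module population with known parameters
small_pop <- function(seed = 42) {
  grid_population(spacings = c(0.5, 0.35), counts = c(60, 80), seed = seed)
}

# brute-force tuning curve: explicit sum of Gaussians over lattice points
# within `rings` rings of the (rotated, shifted) triangular lattice
brute_rate <- function(x, y, lambda, theta, sigma, rmax, phx, phy,
                       rings = 12) {
  B <- lattice_basis(lambda, theta)
  ij <- as.matrix(expand.grid(i = -rings:rings, j = -rings:rings))
  centers <- ij %*% t(B)
  centers[, 1] <- centers[, 1] + phx
  centers[, 2] <- centers[, 2] + phy
  # recenter the lattice near the query point so truncation is symmetric
  uv <- lattice_coords(cbind(x, y), lambda, theta) -
    lattice_coords(cbind(phx, phy), lambda, theta)
  shift <- round(uv) %*% t(B)
  d2 <- (centers[, 1] + shift[1] - x)^2 + (centers[, 2] + shift[2] - y)^2
  rmax * sum(exp(-d2 / (2 * sigma^2)))
}

expect_close <- function(actual, expected, rel = 1e-8) {
  expect_lt(abs(actual - expected), rel * max(abs(expected), 1e-300))
}
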