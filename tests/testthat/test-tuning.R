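test_that("lattice coordinates invert the lattice basis", {
  lambda <- 0.73
  theta <- 0.41
  B <- lattice_basis(lambda, theta)
  uv <- cbind(c(0, 1, 0, 2.3, -1.7), c(0, 0, 1, -0.4, 3.1))
  pts <- uv %*% t(B)
  expect_equal(lattice_coords(pts, lambda, theta), uv, tolerance = 1e-12)
  # basis vectors have length lambda and a 60-degree angle
  expect_equal(sqrt(sum(B[, 1]^2)), lambda, tolerance = 1e-12)
  expect_equal(sqrt(sum(B[, 2]^2)), lambda, tolerance = 1e-12)
  expect_equal(sum(B[, 1] * B[, 2]) / lambda^2, 0.5, tolerance = 1e-12)
})

test_that("firing rate matches a brute-force lattice sum and is periodic", {
  lambda <- 0.42
  theta <- 0.3
  mod <- grid_module(1, lambda, theta, 1,
                     phases = matrix(c(0.13, 0.08), 1, 2))
  set.seed(5)
  pts <- cbind(runif(25, -1, 1), runif(25, -1, 1))
  f <- firing_rate(mod, c(0.13, 0.08), pts)
  fb <- vapply(seq_len(nrow(pts)), function(i)
    brute_rate(pts[i, 1], pts[i, 2], lambda, theta, mod$sigma, mod$rmax,
               0.13, 0.08), numeric(1))
  expect_equal(f, fb, tolerance = 1e-9)
  # periodicity under both lattice vectors
  B <- lattice_basis(lambda, theta)
  for (k in 1:2) {
    shifted <- sweep(pts, 2, B[, k], `+`)
    expect_equal(firing_rate(mod, c(0.13, 0.08), shifted), f,
                 tolerance = 1e-9)
  }
  # peak rate at the phase center is rmax up to neighbor-bump overlap
  peak <- firing_rate(mod, c(0.13, 0.08), matrix(c(0.13, 0.08), 1, 2))
  expect_gte(peak, mod$rmax * (1 - 1e-9))
  expect_lt(peak, mod$rmax * 1.001)
})

test_that("alpha quadrature agrees with the closed form", {
  a_cf <- alpha_gaussian(10, 0.1)
  a_q <- alpha_gaussian(10, 0.1, method = "quadrature", n_grid = 200)
  expect_equal(a_cf, 4 * pi * 10 / sqrt(3), tolerance = 1e-12)
  expect_equal(a_q, a_cf, tolerance = 2e-3)
  # alpha is linear in rmax and independent of the spacing by construction
  expect_equal(alpha_gaussian(20, 0.1), 2 * a_cf, tolerance = 1e-12)
})

test_that("fisher_rate scales as alpha * n / lambda^2", {
  alpha <- alpha_gaussian()
  mod <- grid_module(1, 0.5, 0, 40, sigma_over_lambda = 0.1)
  expect_equal(fisher_rate(mod, alpha), alpha * 40 / 0.25, tolerance = 1e-12)
})

test_that("population construction is deterministic and validated", {
  p1 <- small_pop(7)
  p2 <- small_pop(7)
  p3 <- small_pop(8)
  expect_identical(p1$modules[[1]]$phases, p2$modules[[1]]$phases)
  expect_false(identical(p1$modules[[1]]$phases, p3$modules[[1]]$phases))
  expect_equal(p1$total_n, 140L)
  # phases lie in the fundamental cell: lattice coordinates in [0, 1)
  for (mod in p1$modules) {
    uv <- lattice_coords(mod$phases, mod$spacing, mod$orientation)
    expect_true(all(uv >= -1e-9 & uv < 1 + 1e-9))
  }
  expect_error(grid_population(c(0.3, 0.5), c(10, 10), 1), "decreasing")
  expect_error(grid_population(c(0.5, 0.3), c(10, 2.5), 1), "integer")
  expect_error(grid_module(1, -1, 0, 5), "positive")
})

test_that("summed population rate concentrates with many uniform phases", {
  # with n uniformly placed cells the summed rate at any point approaches
  # n times the cell-averaged rate; the relative spread falls as 1/sqrt(n)
  n <- 3000
  pop <- grid_population(0.5, n, seed = 11)
  set.seed(3)
  pts <- cbind(runif(150, 0, 0.5), runif(150, 0, 0.5))
  tot <- gridcode:::population_rate(pop, pts)
  cv <- sd(tot) / mean(tot)
  expect_lt(cv, 0.1)
  # 1/sqrt(n) concentration: ten times fewer cells, about sqrt(10) more spread
  pop_s <- grid_population(0.5, n / 10, seed = 11)
  tot_s <- gridcode:::population_rate(pop_s, pts)
  cv_s <- sd(tot_s) / mean(tot_s)
  expect_lt(cv, cv_s / 2)
  # mean matches n * rmax * 2 pi sigma^2 / cell area
  cell_area <- sqrt(3) / 2 * 0.5^2
  expected <- n * 10 * 2 * pi * (0.05)^2 / cell_area
  expect_equal(mean(tot), expected, tolerance = 0.02)
})

test_that("population JSON round trip preserves rates", {
  pop <- small_pop(3)
  path <- tempfile(fileext = ".json")
  write_population(pop, path)
  pop2 <- read_population(path)
  pts <- matrix(c(0.1, 0.2, 0.33, 0.41), 2, 2)
  for (i in seq_along(pop$modules)) {
    m1 <- pop$modules[[i]]
    m2 <- pop2$modules[[i]]
    expect_equal(m1$spacing, m2$spacing)
    expect_equal(firing_rate(m1, m1$phases[1, ], pts),
                 firing_rate(m2, m2$phases[1, ], pts), tolerance = 1e-12)
  }
  unlink(path)
})
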