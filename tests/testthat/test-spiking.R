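test_that("spike generation is deterministic and Poisson-consistent", {
  pop <- small_pop(2)
  traj <- simulate_random_walk(0, 1e-3, 0.5, 3, domain_size = 0.5)
  r1 <- generate_spikes(pop, traj, 17)
  r2 <- generate_spikes(pop, traj, 17)
  expect_identical(r1$times, r2$times)
  r3 <- generate_spikes(pop, traj, 18)
  expect_false(identical(r1$times, r3$times))
  # static position: total count is Poisson with mean sum_i f_i(x0) * T
  x0 <- matrix(traj$positions[1, ], 1, 2)
  mu <- gridcode:::population_rate(pop, x0) * traj$duration
  total <- sum(lengths(r1$times))
  expect_lt(abs(total - mu) / sqrt(mu), 4)
  # all spike times inside the duration, sorted per neuron
  expect_true(all(unlist(r1$times) >= 0 & unlist(r1$times) <= r1$duration))
  expect_true(all(vapply(r1$times, function(t) !is.unsorted(t), logical(1))))
})

test_that("per-neuron counts match per-neuron rates", {
  pop <- grid_population(0.4, 30, seed = 5)
  traj <- simulate_random_walk(0, 1e-3, 2, 3, domain_size = 0.4)
  raster <- generate_spikes(pop, traj, 99)
  x0 <- matrix(traj$positions[1, ], 1, 2)
  mod <- pop$modules[[1]]
  z <- vapply(seq_len(30), function(j) {
    mu <- firing_rate(mod, mod$phases[j, ], x0) * traj$duration
    (length(raster$times[[j]]) - mu) / sqrt(max(mu, 1e-12))
  }, numeric(1))
  # standardized residuals: no neuron wildly off, ensemble mean near 0
  expect_lt(max(abs(z)), 5)
  expect_lt(abs(mean(z)), 1)
})

test_that("binning is consistent with spike times", {
  pop <- small_pop(4)
  traj <- simulate_random_walk(0.05, 1e-3, 0.3, 6, domain_size = 0.5)
  raster <- generate_spikes(pop, traj, 7)
  counts <- bin_spikes(raster, 1e-3, 300)
  expect_equal(sum(counts$count), sum(lengths(raster$times)))
  # triplets agree with a direct histogram of each neuron's times
  M <- as.matrix(counts)
  expect_equal(dim(M), c(pop$total_n, 300L))
  for (j in c(1, 70, 140)) {
    h <- tabulate(pmin(floor(raster$times[[j]] / 1e-3 + 1e-9), 299) + 1,
                  nbins = 300)
    expect_equal(M[j, ], h)
  }
  # bins sorted, as the decoders require
  expect_true(!is.unsorted(counts$bin))
})

test_that("high-rate bins can hold multiple spikes and still bin correctly", {
  pop <- grid_population(0.4, 5, seed = 8, sigma_over_lambda = 0.1,
                         rmax = 4000)
  traj <- simulate_random_walk(0, 1e-3, 0.05, 2, domain_size = 0.4)
  raster <- generate_spikes(pop, traj, 3)
  counts <- bin_spikes(raster, 1e-3, 50)
  expect_gt(max(counts$count), 1)
  expect_equal(sum(counts$count), sum(lengths(raster$times)))
})

test_that("raster I/O round trip preserves times and identity", {
  pop <- small_pop(10)
  traj <- simulate_random_walk(0.05, 1e-3, 0.2, 11, domain_size = 0.5)
  raster <- generate_spikes(pop, traj, 12)
  path <- tempfile(fileext = ".csv")
  write_raster(raster, path)
  r2 <- read_raster(path)
  expect_equal(r2$duration, raster$duration)
  expect_equal(r2$module, raster$module)
  expect_equal(r2$cell, raster$cell)
  for (j in seq_len(raster$n_neurons))
    expect_equal(r2$times[[j]], raster$times[[j]], tolerance = 1e-9)
  unlink(c(path, paste0(path, ".json")))
})
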