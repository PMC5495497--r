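test_that("uniform posterior grid is normalized and validated", {
  post <- bayes_init_uniform(1, 1 / 64)
  expect_equal(dim(post$log_p), c(64L, 64L))
  expect_equal(gridcode:::logsumexp(as.vector(post$log_p)), 0,
               tolerance = 1e-12)
  expect_error(bayes_init_uniform(1, 0.3), "divide")
  # the resolution invariant: grids coarser than sigma_min/3 are rejected
  pop <- small_pop(1)  # sigma_min = 0.035
  traj <- simulate_random_walk(0.02, 1e-3, 0.05, 2, domain_size = 0.5)
  ras <- generate_spikes(pop, traj, 3)
  expect_error(
    bayes_decode(ras, pop, motion_random_walk(0.02), domain = 0.5,
                 resolution = 0.025),
    "sigma_min/3")
})

test_that("compiled filter matches the R reference step by step", {
  pop <- small_pop(42)
  mot <- motion_random_walk(0.02)
  traj <- simulate_random_walk(0.02, 1e-3, 0.1, 7, domain_size = 1)
  ras <- generate_spikes(pop, traj, 8)
  dec <- bayes_decode(ras, pop, mot, dt = 1e-3, domain = 1,
                      resolution = 1 / 96, keep_posterior = TRUE)
  post <- bayes_init_uniform(1, 1 / 96)
  cm <- as.matrix(bin_spikes(ras, 1e-3, 100))
  for (b in seq_len(100))
    post <- bayes_step(post, cm[, b], pop, mot, 1e-3, diffuse = b > 1)
  # identical up to template interpolation of the tuning curves
  expect_lt(max(abs(post$log_p - dec$log_posterior)), 0.05)
  ref <- gridcode:::grid_argmax(post)
  expect_lt(max(abs(dec$estimates[100, ] - ref)), 1.5 / 96)
})

test_that("with D = 0 the filter equals the static ML posterior", {
  pop <- small_pop(5)
  mot0 <- motion_random_walk(0)
  traj <- simulate_random_walk(0, 1e-3, 0.15, 4, domain_size = 0.5)
  ras <- generate_spikes(pop, traj, 6)
  dec <- bayes_decode(ras, pop, mot0, dt = 1e-3, domain = 0.5,
                      resolution = 0.5 / 48, keep_posterior = TRUE)
  # direct computation: log p(x) ~ sum_mu [k_mu log f_mu(x) - T f_mu(x)]
  grid <- bayes_init_uniform(0.5, 0.5 / 48)
  W <- gridcode:::log_rate_table(pop, grid)
  k <- rowSums(as.matrix(bin_spikes(ras, 1e-3, 150)))
  lp <- as.vector(W %*% k) - rowSums(exp(W)) * 0.15
  lp <- lp - gridcode:::logsumexp(lp)
  expect_lt(max(abs(lp - dec$log_posterior)), 0.05)
  # the decoded position approaches the true static position
  err <- sqrt(sum((dec$estimates[150, ] - traj$positions[1, ])^2))
  expect_lt(err, 0.03)
})

test_that("recursive kernel decoder matches the direct evaluation", {
  pop <- small_pop(9)
  traj <- simulate_random_walk(0.02, 1e-3, 0.12, 10, domain_size = 1)
  ras <- generate_spikes(pop, traj, 11)
  for (shape in c("exponential", "rectangular")) {
    dec <- kernel_decode(ras, pop, dt = 1e-3, domain = 1,
                         resolution = 1 / 96, taus = c(0.08, 0.05),
                         shape = shape, estimate_every = 40)
    grid <- bayes_init_uniform(1, 1 / 96)
    for (i in seq_along(dec$times)) {
      t_eval <- dec$times[i] + 1e-3  # end of the recorded bin
      ref <- kernel_log_posterior(
        ras, pop, list(shape = shape, tau = c(0.08, 0.05)), t_eval, grid)
      ref_est <- gridcode:::grid_argmax(ref)
      expect_lt(max(abs(dec$estimates[i, ] - ref_est)), 1.5 / 96)
    }
  }
})

test_that("readout weights plus filtered counts reproduce the kernel decoder", {
  pop <- small_pop(13)
  traj <- simulate_random_walk(0.02, 1e-3, 0.1, 14, domain_size = 1)
  ras <- generate_spikes(pop, traj, 15)
  taus <- c(0.07, 0.04)
  dec <- kernel_decode(ras, pop, dt = 1e-3, domain = 1, resolution = 1 / 96,
                       taus = taus, estimate_every = 100, refine = FALSE)
  grid <- bayes_init_uniform(1, 1 / 96)
  W <- build_readout_weights(pop, gridcode:::grid_nodes(grid))
  pa <- gridcode:::pop_arrays(pop)
  t_eval <- dec$times[1] + 1e-3
  s <- vapply(seq_len(pop$total_n), function(n) {
    ts <- ras$times[[n]][ras$times[[n]] <= t_eval]
    sum(exp(-(t_eval - ts) / taus[pa$module[n] + 1]))
  }, numeric(1))
  act <- as.vector(W %*% s)
  est <- gridcode:::grid_nodes(grid)[which.max(act), ]
  expect_lt(max(abs(dec$estimates[1, ] - est)), 1.5 / 96)
})

test_that("local errors, peaks and estimate cadence are recorded", {
  pop <- small_pop(20)
  mot <- motion_random_walk(0.02)
  traj <- simulate_random_walk(0.02, 1e-3, 0.1, 21, domain_size = 0.5)
  ras <- generate_spikes(pop, traj, 22)
  dec <- bayes_decode(ras, pop, mot, dt = 1e-3, domain = 0.5,
                      resolution = 0.5 / 64, truth = traj,
                      estimate_every = 4)
  expect_equal(dec$times, seq(3, 99, by = 4) * 1e-3)
  expect_true(all(is.finite(dec$local_err2)))
  expect_true(all(dec$local_err2 >= 0))
  expect_true(all(dec$n_peaks >= 1))
  # estimates live inside the periodic domain
  expect_true(all(dec$estimates >= 0 & dec$estimates < 0.5))
  # node-center convention: without refinement estimates sit on grid nodes
  dec0 <- bayes_decode(ras, pop, mot, dt = 1e-3, domain = 0.5,
                       resolution = 0.5 / 64, refine = FALSE,
                       estimate_every = 25)
  off <- (dec0$estimates / (0.5 / 64)) %% 1
  expect_true(all(abs(off - 0.5) < 1e-9))
})

test_that("posterior underflow raises the documented error", {
  pop <- small_pop(30)
  traj <- simulate_random_walk(0.02, 1e-3, 0.01, 31, domain_size = 0.5)
  ras <- generate_spikes(pop, traj, 32)
  prior <- bayes_init_uniform(0.5, 0.5 / 48)
  prior$log_p[] <- -Inf
  expect_error(
    bayes_decode(ras, pop, motion_random_walk(0.02), dt = 1e-3,
                 domain = 0.5, resolution = 0.5 / 48, prior = prior),
    "posterior underflow")
})
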