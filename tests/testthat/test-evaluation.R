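test_that("error reports and pooling follow the CI definition", {
  per <- c(1, 2, 3, 4) * 1e-4
  rep1 <- error_report(per, 400, metric = "local")
  expect_equal(rep1$mse, mean(per))
  expect_equal(rep1$rmse, sqrt(mean(per)))
  expect_equal(rep1$ci_halfwidth, 1.96 * sd(per) / 2, tolerance = 1e-12)
  singles <- lapply(per, function(m) error_report(m, 100, metric = "local"))
  pooled <- pool_reports(singles)
  expect_equal(pooled$mse, rep1$mse)
  expect_equal(pooled$ci_halfwidth, rep1$ci_halfwidth, tolerance = 1e-12)
  expect_equal(pooled$n_timepoints, 400L)
  expect_error(error_report(numeric(0), 1), "length")
})

test_that("peak finding locates separated bumps and honors the threshold", {
  grid <- bayes_init_uniform(1, 1 / 64)
  nodes <- gridcode:::grid_nodes(grid)
  lp <- -((nodes[, 1] - 0.25)^2 + (nodes[, 2] - 0.25)^2) / (2 * 0.03^2)
  lp2 <- -((nodes[, 1] - 0.75)^2 + (nodes[, 2] - 0.7)^2) / (2 * 0.03^2) - 3
  grid$log_p <- matrix(pmax(lp, lp2), 64, 64)
  pk <- gridcode:::find_peaks_grid(grid, rel_tol = 1e-3)
  expect_equal(nrow(pk), 2L)
  ord <- order(pk[, 1])
  expect_equal(pk[ord[1], ], c(0.25, 0.25), tolerance = 2e-3)
  expect_equal(pk[ord[2], ], c(0.75, 0.7), tolerance = 2e-3)
  # a tighter threshold hides the secondary peak (exp(-3) ~ 0.05 of max)
  pk1 <- gridcode:::find_peaks_grid(grid, rel_tol = 0.1)
  expect_equal(nrow(pk1), 1L)
})

test_that("global RMSE uses toroidal distance", {
  est <- rbind(c(0.05, 0.5), c(0.95, 0.5))
  truth <- rbind(c(0.95, 0.5), c(0.05, 0.5))  # 0.1 apart across the seam
  fake <- structure(list(times = c(0, 1e-3), estimates = est, dt = 1e-3,
                         domain = c(1, 1)), class = "decode_result")
  rep <- global_rmse(fake, truth)
  expect_equal(rep$rmse, 0.1, tolerance = 1e-12)
  # burn-in drops early estimates
  rep2 <- global_rmse(fake, truth, burn_in = 1e-3)
  expect_equal(rep2$n_timepoints, 1L)
})

test_that("local MSE from posterior grids matches the decode-time record", {
  pop <- small_pop(2)
  mot <- motion_random_walk(0.02)
  traj <- simulate_random_walk(0.02, 1e-3, 0.06, 3, domain_size = 0.5)
  ras <- generate_spikes(pop, traj, 4)
  dec <- bayes_decode(ras, pop, mot, dt = 1e-3, domain = 0.5,
                      resolution = 0.5 / 64, truth = traj)
  rep <- local_mse(dec, burn_in = 0.03)
  expect_s3_class(rep, "error_report")
  expect_equal(rep$metric, "local")
  expect_equal(rep$n_timepoints, 30L)
  # reference path: rebuild the final posterior and locate peaks directly
  dec2 <- bayes_decode(ras, pop, mot, dt = 1e-3, domain = 0.5,
                       resolution = 0.5 / 64, truth = traj,
                       keep_posterior = TRUE)
  grid <- bayes_init_uniform(0.5, 0.5 / 64)
  grid$log_p <- matrix(dec2$log_posterior, 64, 64)
  rep_ref <- local_mse(list(grid), truth = traj$positions[60, , drop = FALSE])
  expect_equal(rep_ref$mse, dec2$local_err2[60], tolerance = 1e-6)
})

test_that("single-module runner returns theory attributes and behaves", {
  rep <- run_single_module(150, D = NULL, n_sims = 8, seed = 2,
                           delta_T = 0.05)
  expect_s3_class(rep, "error_report")
  expect_equal(attr(rep, "J"), alpha_gaussian() * 150, tolerance = 1e-12)
  expect_equal(attr(rep, "theory"),
               local_mse_static(alpha_gaussian() * 150, 0.05),
               tolerance = 1e-12)
  expect_equal(rep$n_sims, 8L)
  # the observed MSE is within a factor ~2 of theory even at this tiny scale
  expect_gt(rep$mse / attr(rep, "theory"), 0.3)
  expect_lt(rep$mse / attr(rep, "theory"), 3)
})

test_that("experiment runner attaches provenance and reproduces exactly", {
  cfg <- list(preset = "msd_recovery", seed = 5, g = 0.02, epsilon = 1.5,
              n_realizations = 3, duration = 8, dt = 0.04)
  out1 <- run_experiment(cfg)
  out2 <- run_experiment(cfg)
  expect_identical(out1$reports, out2$reports)
  expect_equal(out1$provenance$seed, 5)
  expect_equal(out1$provenance$preset, "msd_recovery")
  expect_true(is.character(out1$provenance$package_version))
  expect_error(run_experiment(list(preset = "msd_recovery", seed = 1,
                                   n_realizations = 0)), "validation error")
  expect_error(run_experiment(list(seed = 1)), "preset")
})

test_that("beta sweep returns one pooled row per beta", {
  df <- run_beta_sweep(c(0.1, 0.3), N = 300, m = 2, lambda1 = 1,
                       motion = motion_random_walk(0.01), n_sims = 1,
                       duration = 0.2, burn_in = 0.1, seed = 3)
  expect_equal(nrow(df), 2L)
  expect_equal(df$beta, c(0.1, 0.3))
  expect_true(all(df$mse > 0))
  expect_equal(df$rmse, sqrt(df$mse), tolerance = 1e-12)
})
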