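test_that("random walk has the right increments and determinism", {
  tr1 <- simulate_random_walk(0.05, 1e-3, 1, 9, domain_size = 2)
  tr2 <- simulate_random_walk(0.05, 1e-3, 1, 9, domain_size = 2)
  expect_identical(tr1$positions_raw, tr2$positions_raw)
  expect_equal(nrow(tr1$positions), 1001)
  expect_true(all(tr1$positions >= 0 & tr1$positions < 2))
  inc <- diff(tr1$positions_raw)
  v <- mean(inc^2)  # per-axis increment variance, expect 2 D dt
  se <- sd(as.vector(inc^2)) / sqrt(length(inc))
  expect_lt(abs(v - 2 * 0.05 * 1e-3), 4 * se)
  # D = 0 keeps the walker at the start
  tr0 <- simulate_random_walk(0, 1e-3, 0.01, 1, domain_size = 1)
  expect_true(all(tr0$positions == 0.5))
})

test_that("random-walk MSD grows as 4 D lag", {
  D <- 0.02
  msds <- sapply(1:6, function(s) {
    tr <- simulate_random_walk(D, 0.01, 20, 100 + s)
    compute_msd(tr, 0.5)$msd
  })
  lags <- seq(0.01, 0.5, by = 0.01)
  ratio <- rowMeans(msds) / (4 * D * lags)
  expect_true(all(abs(ratio - 1) < 0.15))
})

test_that("compute_msd averages overlapping pairs (hand oracle)", {
  xy <- cbind(c(0, 1, 3, 6), c(0, 0, 0, 0))
  tr <- structure(
    list(dt = 1, positions = xy, positions_raw = xy, domain = NULL,
         duration = 3), class = "trajectory")
  msd <- compute_msd(tr, 2)
  expect_equal(msd$msd[1], mean(c(1, 4, 9)))
  expect_equal(msd$msd[2], mean(c(9, 25)))
  expect_equal(msd$n_pairs, c(3L, 2L))
})

test_that("fractional motion has exact power-law increment statistics", {
  g <- 0.023
  eps <- 1.68
  dt <- 0.04
  tr <- simulate_power_law(g, eps, dt, 160, 21)
  inc <- diff(tr$positions_raw)
  v1 <- mean(inc^2)
  expect_equal(v1, (g / 2) * dt^eps, tolerance = 0.05)
  # lag-1 autocorrelation of fractional Gaussian noise:
  # rho(1) = (2^(2H) - 2) / 2 with H = eps / 2
  rho_hat <- (cor(inc[-nrow(inc), 1], inc[-1, 1]) +
                cor(inc[-nrow(inc), 2], inc[-1, 2])) / 2
  rho_th <- (2^eps - 2) / 2
  expect_lt(abs(rho_hat - rho_th), 0.05)
  # epsilon = 1 (simulated just below) reduces to a random walk: zero corr
  tr1 <- simulate_power_law(0.08, 1 - 1e-9, dt, 160, 22)
  inc1 <- diff(tr1$positions_raw)
  expect_lt(abs(cor(inc1[-nrow(inc1), 1], inc1[-1, 1])), 0.05)
  expect_equal(mean(inc1^2), (0.08 / 2) * dt, tolerance = 0.05)
})

test_that("power-law fit is exact on exact curves", {
  lags <- seq(0.04, 1.2, by = 0.04)
  msd <- structure(list(lags = lags, msd = 0.023 * lags^1.68,
                        n_pairs = rep(100L, length(lags))),
                   class = "msd_curve")
  fit <- fit_power_law(msd, window = c(0.32, 0.8))
  expect_equal(fit$g, 0.023, tolerance = 1e-10)
  expect_equal(fit$epsilon, 1.68, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(unname(coef(fit)), c(fit$g, fit$epsilon))
})

test_that("fit recovers the exponent from simulated fractional motion", {
  tr <- simulate_power_law(0.023, 1.68, 0.04, 30, 2)
  fit <- fit_power_law(compute_msd(tr, 1.2), window = c(0.32, 0.8))
  expect_lt(abs(fit$epsilon - 1.68), 0.15)
  expect_gt(fit$r_squared, 0.95)
})

test_that("input validation and trajectory I/O round trip", {
  expect_error(simulate_power_law(0.02, 2.3, 0.01, 1, 1), "epsilon")
  expect_error(simulate_power_law(-1, 1.5, 0.01, 1, 1), "positive")
  expect_error(simulate_random_walk(0.05, 1, 0.5, 1), "duration")
  tr <- simulate_random_walk(0.03, 0.01, 0.5, 4, domain_size = c(2, 3))
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  tr2 <- read_trajectory(path, domain_size = c(2, 3))
  expect_equal(tr2$positions_raw, tr$positions_raw, tolerance = 1e-12)
  expect_equal(tr2$dt, tr$dt)
  expect_equal(tr2$positions, tr$positions, tolerance = 1e-12)
  unlink(path)
  msd <- compute_msd(tr, 0.2)
  jpath <- tempfile(fileext = ".json")
  write_msd_report(msd, jpath, fit = NULL)
  doc <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(doc$msd, msd$msd, tolerance = 1e-12)
  unlink(jpath)
})
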