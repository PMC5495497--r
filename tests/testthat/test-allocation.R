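test_that("closed-form ratios and error laws are consistent", {
  expect_equal(population_ratio(1), 2)
  expect_equal(population_ratio(2), 1.5)
  expect_equal(spacing_ratio_limit(1), sqrt(2), tolerance = 1e-12)
  expect_equal(spacing_ratio_limit(2), 1.5, tolerance = 1e-12)
  # power-law MSE reduces to the random-walk law at epsilon = 1, g = 4 D
  J <- 5e4
  D <- 0.05
  expect_equal(local_mse_power_law(J, 4 * D, 1), local_mse_dynamic(J, D),
               tolerance = 1e-12)
  # static law
  expect_equal(local_mse_static(J, 0.1), 2 / (J * 0.1), tolerance = 1e-12)
})

test_that("kernel theory: optimum location, value, and shape ordering", {
  J <- 2e4
  mot <- motion_random_walk(0.05)
  tau_e <- optimal_tau(J, mot, "exponential")
  # random walk: tau* = 1 / sqrt(2 D J), V(tau*) equals the optimal filter
  expect_equal(tau_e, 1 / sqrt(2 * mot$D * J), tolerance = 1e-12)
  expect_equal(kernel_mse_theory(J, tau_e, mot, "exponential"),
               local_mse_dynamic(J, mot$D), tolerance = 1e-12)
  # tau* is a true minimum of the tau curve
  taus <- tau_e * c(0.5, 0.9, 1, 1.1, 2)
  v <- kernel_mse_theory(J, taus, mot, "exponential")
  expect_equal(which.min(v), 3L)
  # rectangular window: optimum from the closed form, and its best error
  # exceeds the exponential kernel's best error
  T_r <- optimal_tau(J, mot, "rectangular")
  vr <- kernel_mse_theory(J, T_r * c(0.8, 1, 1.25), mot, "rectangular")
  expect_equal(which.min(vr), 2L)
  expect_gt(min(vr), kernel_mse_theory(J, tau_e, mot, "exponential"))
  # same ordering under power-law motion
  mot2 <- motion_power_law(0.023, 1.68)
  te <- optimal_tau(J, mot2, "exponential")
  tr <- optimal_tau(J, mot2, "rectangular")
  expect_gt(kernel_mse_theory(J, tr, mot2, "rectangular"),
            kernel_mse_theory(J, te, mot2, "exponential"))
})

test_that("allocation reproduces the reference plan", {
  plan <- allocate_modules(1e4, 10, 5, 0.1, motion_random_walk(0.05))
  expect_equal(sum(plan$n), 10000L)
  expect_equal(plan$n[1], 10L)  # largest-spacing module
  expect_equal(plan$n[10], 5005L)
  # neighboring counts approach ratio 2
  expect_equal(plan$n[10] / plan$n[9], 2, tolerance = 1e-3)
  # spacings decrease and the chain enforces delta_i = beta * lambda_{i+1}
  # exactly at the fractional geometric counts used to build it
  expect_true(all(diff(plan$lambdas) < 0))
  d_exact <- sqrt(local_mse_power_law(
    plan$params$alpha * plan$n_exact / plan$lambdas^2, 4 * 0.05, 1))
  expect_equal(d_exact[-10], 0.1 * plan$lambdas[-1], tolerance = 1e-9)
  # the reported deltas use the integer counts: close but not identical
  expect_equal(plan$deltas[-10], 0.1 * plan$lambdas[-1], tolerance = 2e-2)
  expect_equal(min(plan$lambdas), 0.2099, tolerance = 1e-3)
  expect_equal(100 * plan$deltas[10], 1.484, tolerance = 1e-3)
  # readout constants span milliseconds to ~0.6 s and halve down the chain
  expect_equal(max(plan$taus), 0.587, tolerance = 2e-3)
  expect_equal(plan$taus[9] / plan$taus[10], 2, tolerance = 1e-2)
  # spacing ratios decrease towards sqrt(2)
  ratios <- plan$lambdas[-10] / plan$lambdas[-1]
  expect_equal(ratios[1], 1.451, tolerance = 1e-3)
  expect_lt(abs(ratios[9] - sqrt(2)), 2e-3)
})

test_that("allocation fractions are invariant to scale parameters", {
  base <- allocate_modules(2000, 6, 5, 0.1, motion_random_walk(0.05))
  for (p in list(list(N = 20000), list(lambda1 = 50), list(beta = 1),
                 list(D = 0.5))) {
    plan <- allocate_modules(p$N %||% 2000, 6, p$lambda1 %||% 5,
                             p$beta %||% 0.1,
                             motion_random_walk(p$D %||% 0.05))
    N <- sum(plan$n)
    expect_lt(max(abs(plan$n / N - base$n / 2000)), 1.5 / 2000)
  }
})

test_that("max_modules matches an explicit enumeration oracle", {
  # the smallest (largest-spacing) module's exact geometric share is
  # N (r - 1) / (r^m - 1); closed form for the largest m keeping it >= 1
  oracle <- function(N, r) as.integer(floor(log(N * (r - 1) + 1, base = r)))
  for (case in list(c(1e5, 2), c(1e4, 2), c(500, 1.5), c(37, 2))) {
    expect_equal(max_modules(case[1], case[2]), oracle(case[1], case[2]))
  }
  expect_equal(max_modules(1e5, 2), 16L)
  expect_equal(max_modules(1e4, 2), 13L)
})

test_that("infeasible plans fail with the maximum feasible module count", {
  expect_error(allocate_modules(100, 10, 5, 0.1, motion_random_walk(0.05)),
               "maximum feasible")
  expect_error(motion_power_law(0.02, 2.5), "epsilon")
  expect_error(motion_random_walk(-1), "non-negative")
})

test_that("reallocate reshuffles counts but never spacings", {
  plan <- allocate_modules(3000, 5, 5, 0.1, motion_random_walk(0.05))
  eq <- reallocate(plan, "equal")
  rv <- reallocate(plan, "reversed")
  expect_equal(eq$lambdas, plan$lambdas)
  expect_equal(rv$lambdas, plan$lambdas)
  expect_equal(sum(eq$n), 3000L)
  expect_equal(rv$n, rev(plan$n))
  expect_lt(diff(range(eq$n)), 2)
  expect_equal(reallocate(plan, "optimal")$n, plan$n)
})

test_that("plan JSON round trip is faithful", {
  plan <- allocate_modules(1e4, 10, 5, 0.1, motion_random_walk(0.05))
  path <- tempfile(fileext = ".json")
  write_plan(plan, path)
  p2 <- read_plan(path)
  expect_equal(p2$n, plan$n)
  expect_equal(p2$lambdas, plan$lambdas, tolerance = 1e-12)
  expect_equal(p2$taus, plan$taus, tolerance = 1e-12)
  expect_equal(p2$params$motion$D, 0.05)
  unlink(path)
})
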