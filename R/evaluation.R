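# Error metrics (local nearest-peak and global toroidal RMSE), confidence
# intervals, and experiment runners.

#' Error report
#'
#' Summarizes a decoding error: mean square error, RMSE, and a 95% confidence
#' half-width computed as 1.96 times the standard deviation of the
#' per-simulation MSEs divided by the square root of the number of
#' simulations (time average within each simulation first, then across
#' simulations).
#'
#' @param per_sim_mse numeric vector of per-simulation time-averaged MSEs
#'   (m^2).
#' @param n_timepoints total number of timepoints entering the average.
#' @param metric \code{"local"} or \code{"global"}.
#' @return an object of class \code{error_report} with fields \code{mse},
#'   \code{rmse}, \code{ci_halfwidth} (m^2), \code{n_sims},
#'   \code{n_timepoints}, \code{metric}, \code{per_sim_mse}.
#' @export
error_report <- function(per_sim_mse, n_timepoints, metric = "global") {
  stopifnot(length(per_sim_mse) >= 1, all(per_sim_mse >= 0))
  n <- length(per_sim_mse)
  mse <- mean(per_sim_mse)
  ci <- if (n > 1) 1.96 * sd(per_sim_mse) / sqrt(n) else 0
  structure(list(mse = mse, rmse = sqrt(mse), ci_halfwidth = ci,
                 n_sims = n, n_timepoints = as.integer(n_timepoints),
                 metric = metric, per_sim_mse = per_sim_mse),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf(
    "error_report (%s): MSE = %.6g m^2 (+- %.2g 95%% CI), RMSE = %.4g cm, %d sims, %d timepoints\n",
    x$metric, x$mse, x$ci_halfwidth, 100 * x$rmse, x$n_sims,
    x$n_timepoints))
  invisible(x)
}

# peaks of one posterior grid: strict local maxima over the wrapped
# 8-neighborhood, at least rel_tol of the global maximum
find_peaks_grid <- function(grid, rel_tol = 1e-3, refine = TRUE) {
  lp <- grid$log_p
  nx <- nrow(lp)
  ny <- ncol(lp)
  sh <- function(di, dj) {
    ri <- ((seq_len(nx) - 1 + di) %% nx) + 1
    rj <- ((seq_len(ny) - 1 + dj) %% ny) + 1
    lp[ri, rj, drop = FALSE]
  }
  is_peak <- lp >= max(lp) + log(rel_tol)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- sh(di, dj)
    # strict against later neighbors, non-strict against earlier ones, so an
    # exactly tied plateau still yields exactly one representative peak
    if (di > 0 || (di == 0 && dj > 0))
      is_peak <- is_peak & (lp > nb)
    else
      is_peak <- is_peak & (lp >= nb)
  }
  idx <- which(is_peak, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(numeric(0), 0, 2))
  res <- grid$resolution
  ref1 <- function(l, c, r) {
    den <- l - 2 * c + r
    d <- ifelse(is.finite(den) & den < 0, (l - r) / (2 * den), 0)
    pmax(pmin(d, 0.5), -0.5)
  }
  dx <- dy <- rep(0, nrow(idx))
  if (refine) {
    ii <- idx[, 1]; jj <- idx[, 2]
    im <- ((ii - 2) %% nx) + 1; ip <- (ii %% nx) + 1
    jm <- ((jj - 2) %% ny) + 1; jp <- (jj %% ny) + 1
    cc <- lp[cbind(ii, jj)]
    dx <- ref1(lp[cbind(im, jj)], cc, lp[cbind(ip, jj)])
    dy <- ref1(lp[cbind(ii, jm)], cc, lp[cbind(ii, jp)])
  }
  cbind((idx[, 1] - 0.5 + dx) * res, (idx[, 2] - 0.5 + dy) * res)
}

#' Local decoding error (nearest posterior peak)
#'
#' The local mean square error is the squared toroidal distance between the
#' true position and the closest local maximum of the posterior, averaged
#' over time. It quantifies readout resolution while being blind to the
#' code's global (periodic) ambiguity. Accepts either a list of
#' \code{posterior_grid}s with a matching truth, or a \code{decode_result}
#' produced with \code{truth} (whose per-bin nearest-peak errors were
#' recorded during decoding).
#'
#' @param x a \code{decode_result} or a list of \code{posterior_grid}s.
#' @param truth a \code{trajectory} or an \code{n x 2} matrix of true
#'   positions aligned with \code{x} (required for posterior lists).
#' @param ... passed to methods.
#' @return an \code{error_report} with \code{metric = "local"}.
#' @export
local_mse <- function(x, truth = NULL, ...) UseMethod("local_mse")

#' @rdname local_mse
#' @param burn_in discard estimates at times below this (s).
#' @export
local_mse.decode_result <- function(x, truth = NULL, burn_in = 0, ...) {
  if (is.null(x$local_err2))
    stop("decode was run without `truth`; no local errors recorded")
  keep <- x$times >= burn_in
  e2 <- x$local_err2[keep]
  if (any(is.na(e2))) stop("no peaks found in at least one posterior")
  error_report(mean(e2), sum(keep), metric = "local")
}

#' @rdname local_mse
#' @param rel_tol peak threshold relative to the posterior maximum.
#' @param domain periodic domain (defaults to the grids' domain).
#' @export
local_mse.list <- function(x, truth = NULL, rel_tol = 1e-3, domain = NULL,
                           ...) {
  if (is.null(truth)) stop("`truth` is required")
  domain <- as_domain(domain %||% x[[1]]$domain)
  xy <- if (inherits(truth, "trajectory")) truth$positions else
    matrix(truth, ncol = 2)
  if (nrow(xy) < length(x)) stop("`truth` shorter than the posterior list")
  e2 <- vapply(seq_along(x), function(k) {
    pk <- find_peaks_grid(x[[k]], rel_tol = rel_tol)
    if (nrow(pk) == 0) stop("no peaks found in posterior ", k)
    tr <- matrix(wrap_positions(xy[k, , drop = FALSE], domain),
                 nrow(pk), 2, byrow = TRUE)
    min(toroidal_dist2(pk, tr, domain))
  }, numeric(1))
  error_report(mean(e2), length(e2), metric = "local")
}

#' Global decoding error (toroidal RMSE)
#'
#' Root mean square toroidal displacement between decoded estimates and the
#' true position, time-averaged. Unlike \code{\link{local_mse}} this metric
#' is sensitive to global (periodic) ambiguity errors.
#'
#' @param result a \code{decode_result}.
#' @param truth a \code{trajectory} or matrix of true positions sampled at
#'   the decoding time step.
#' @param burn_in discard estimates at times below this (s).
#' @return an \code{error_report} with \code{metric = "global"}.
#' @export
global_rmse <- function(result, truth, burn_in = 0) {
  xy <- if (inherits(truth, "trajectory")) truth$positions else
    matrix(truth, ncol = 2)
  idx <- round(result$times / result$dt) + 1
  if (max(idx) > nrow(xy)) stop("`truth` shorter than the decode result")
  tr <- wrap_positions(xy[idx, , drop = FALSE], result$domain)
  keep <- result$times >= burn_in
  e2 <- toroidal_dist2(result$estimates[keep, , drop = FALSE],
                       tr[keep, , drop = FALSE], result$domain)
  error_report(mean(e2), sum(keep), metric = "global")
}

# pool per-simulation reports into one report with a cross-simulation CI
pool_reports <- function(reports) {
  error_report(vapply(reports, `[[`, 1, "mse"),
               sum(vapply(reports, `[[`, 1L, "n_timepoints")),
               metric = reports[[1]]$metric)
}

#' Single-module decoding experiment
#'
#' Simulates a single grid module observing either a static position (for
#' \code{delta_T} seconds) or a random walk, decodes every realization, and
#' reports the local (nearest-peak) MSE with its theoretical prediction:
#' \code{2/(J delta_T)} (static) or \code{2 sqrt(2 D / J)} (dynamic).
#'
#' @param n_cells number of cells in the module.
#' @param D diffusion coefficient (m^2/s); \code{NULL} for a static position.
#' @param n_sims number of independent realizations.
#' @param seed base seed; per-simulation seeds are derived from it.
#' @param lambda grid spacing (m); the periodic domain is a square of side
#'   \code{lambda}.
#' @param delta_T observation window for the static case (s).
#' @param duration trajectory duration for the dynamic case (s).
#' @param burn_in discarded initial period, dynamic case (s).
#' @param dt simulation and decoding time step (s).
#' @param resolution decoding grid resolution (m).
#' @param decoder \code{"bayes"} or \code{"kernel"}.
#' @param tau kernel time constant (s); defaults to the optimal value for the
#'   module when \code{decoder = "kernel"}.
#' @param kernel_shape kernel shape for \code{decoder = "kernel"}.
#' @param rmax,sigma_over_lambda tuning parameters.
#' @param estimate_every record one estimate per this many bins (dynamic).
#' @param refine sub-grid peak interpolation.
#' @return an \code{error_report} (local metric) with attributes
#'   \code{theory} (predicted MSE, m^2) and \code{J}.
#' @export
run_single_module <- function(n_cells, D = NULL, n_sims = 100, seed = 1,
                              lambda = 1, delta_T = 0.1, duration = 0.4,
                              burn_in = 0.15, dt = 1e-3,
                              resolution = lambda / 96,
                              decoder = c("bayes", "kernel"), tau = NULL,
                              kernel_shape = "exponential", rmax = 10,
                              sigma_over_lambda = 0.1, estimate_every = 1,
                              refine = TRUE) {
  decoder <- match.arg(decoder)
  if (n_sims < 1) stop("`n_sims` must be at least 1")
  domain <- c(lambda, lambda)
  alpha <- alpha_gaussian(rmax, sigma_over_lambda)
  J <- alpha * n_cells / lambda^2
  static <- is.null(D)
  theory <- if (static) local_mse_static(J, delta_T)
            else local_mse_dynamic(J, D)
  mot_dec <- motion_random_walk(if (static) 0 else D)
  if (decoder == "kernel" && is.null(tau))
    tau <- if (static) delta_T else optimal_tau(J, mot_dec,
      shape = if (kernel_shape == "rectangular") "rectangular"
              else "exponential")
  reports <- vector("list", n_sims)
  for (s in seq_len(n_sims)) {
    sd_i <- derive_seed(seed, s)
    pop <- grid_population(lambda, n_cells, sd_i,
                           sigma_over_lambda = sigma_over_lambda,
                           rmax = rmax)
    if (static) {
      start <- c(runif(1, 0, domain[1]), runif(1, 0, domain[2]))
      nb <- round(delta_T / dt)
      truth <- matrix(start, nb, 2, byrow = TRUE)
      traj <- new_trajectory(dt, matrix(start, nb + 1, 2, byrow = TRUE),
                             domain)
      ee <- nb  # single estimate at the end of the window
      bi <- 0
    } else {
      traj <- simulate_random_walk(D, dt, duration, derive_seed(sd_i, 7),
                                   domain_size = domain)
      truth <- traj
      ee <- estimate_every
      bi <- burn_in
    }
    raster <- generate_spikes(pop, traj, derive_seed(sd_i, 11))
    res <- if (decoder == "bayes")
      bayes_decode(raster, pop, mot_dec, dt = dt, domain = domain,
                   resolution = resolution, truth = truth,
                   estimate_every = ee, refine = refine)
    else
      kernel_decode(raster, pop, dt = dt, domain = domain,
                    resolution = resolution, taus = tau,
                    shape = kernel_shape, truth = truth,
                    estimate_every = ee, refine = refine)
    reports[[s]] <- local_mse(res, burn_in = bi)
  }
  out <- pool_reports(reports)
  attr(out, "theory") <- theory
  attr(out, "J") <- J
  out
}

#' Allocation-comparison decoding experiment
#'
#' Builds populations realizing a module plan under different neuron
#' allocations (optimal / equal / reversed across the same spacings), runs
#' matched random-walk trajectories through each, decodes with the Bayesian
#' filter, and reports the global toroidal RMSE per allocation.
#'
#' @param plan a \code{module_plan} (random-walk motion).
#' @param schemes allocation schemes to compare.
#' @param n_sims number of simulations per scheme.
#' @param duration trajectory duration per simulation (s).
#' @param burn_in discarded initial period (s).
#' @param dt time step (s).
#' @param resolution decoding grid resolution (m); defaults to the coarsest
#'   grid satisfying \code{resolution <= sigma_min/3} that divides the domain.
#' @param seed base seed.
#' @param estimate_every record one estimate per this many bins.
#' @param refine if TRUE, quadratic sub-grid refinement of estimates; the
#'   default reports node centers.
#' @return named list of \code{error_report}s (global metric).
#' @export
run_allocation_comparison <- function(plan,
                                      schemes = c("optimal", "equal",
                                                  "reversed"),
                                      n_sims = 10, duration = 0.75,
                                      burn_in = 0.3, dt = 1e-3,
                                      resolution = NULL, seed = 1,
                                      estimate_every = 2, refine = FALSE) {
  if (n_sims < 1) stop("`n_sims` must be at least 1")
  mot <- plan$params$motion
  if (mot$kind != "random_walk")
    stop("allocation comparison requires a random-walk plan")
  lambda1 <- plan$params$lambda1
  sig_min <- min(plan$lambdas) * plan$params$sigma_over_lambda
  resolution <- resolution %||%
    (lambda1 / ceiling(lambda1 / (sig_min / 3)))
  domain <- c(lambda1, lambda1)
  out <- list()
  for (scheme in schemes) {
    pl <- reallocate(plan, scheme)
    reports <- vector("list", n_sims)
    for (s in seq_len(n_sims)) {
      sd_i <- derive_seed(seed, s)
      traj <- simulate_random_walk(mot$D, dt, duration, sd_i,
                                   domain_size = domain)
      pop <- build_population(pl, derive_seed(sd_i, 3),
                              sigma_over_lambda =
                                plan$params$sigma_over_lambda,
                              rmax = plan$params$rmax)
      raster <- generate_spikes(pop, traj, derive_seed(sd_i, 5))
      res <- bayes_decode(raster, pop, mot, dt = dt, domain = domain,
                          resolution = resolution,
                          estimate_every = estimate_every, refine = refine)
      reports[[s]] <- global_rmse(res, traj, burn_in = burn_in)
    }
    out[[scheme]] <- pool_reports(reports)
  }
  out
}

#' Nesting-ratio (beta) sweep
#'
#' Re-optimizes the module plan for each value of the nesting safety ratio
#' beta, simulates and decodes with the kernel (filtered spike count) decoder
#' at each module's optimal time constant, and reports the global MSE as a
#' function of beta. Small beta wastes resolution (coarse smallest spacing);
#' large beta risks ambiguity errors between neighboring scales —
#' occasional full-period displacements of the estimate — so the MSE has an
#' interior minimum.
#'
#' @param betas vector of beta values.
#' @param N,m,lambda1 plan parameters.
#' @param motion a random-walk \code{motion_model}.
#' @param n_sims simulations per beta.
#' @param duration,burn_in,dt,seed,estimate_every as in
#'   \code{\link{run_allocation_comparison}}.
#' @param resolution decoding grid resolution (m); defaults per beta to
#'   \code{sigma_min/3} rounded down to divide the domain.
#' @param decoder \code{"kernel"} (the readout whose ambiguity failures shape
#'   the large-beta branch) or \code{"bayes"}.
#' @param rmax,sigma_over_lambda tuning parameters.
#' @return data frame with columns \code{beta}, \code{mse}, \code{rmse},
#'   \code{ci_halfwidth}.
#' @export
run_beta_sweep <- function(betas, N, m, lambda1, motion, n_sims = 4,
                           duration = 0.6, burn_in = 0.2, dt = 1e-3,
                           seed = 1, resolution = NULL,
                           decoder = c("kernel", "bayes"), rmax = 10,
                           sigma_over_lambda = 0.1, estimate_every = 2) {
  decoder <- match.arg(decoder)
  rows <- lapply(betas, function(beta) {
    plan <- allocate_modules(N, m, lambda1, beta, motion, rmax = rmax,
                             sigma_over_lambda = sigma_over_lambda)
    sig_min <- min(plan$lambdas) * sigma_over_lambda
    res <- resolution %||% (lambda1 / ceiling(lambda1 / (sig_min / 3)))
    reports <- vector("list", n_sims)
    for (s in seq_len(n_sims)) {
      sd_i <- derive_seed(seed, s)
      traj <- simulate_random_walk(motion$D, dt, duration, sd_i,
                                   domain_size = lambda1)
      pop <- build_population(plan, derive_seed(sd_i, 3),
                              sigma_over_lambda = sigma_over_lambda,
                              rmax = rmax)
      raster <- generate_spikes(pop, traj, derive_seed(sd_i, 5))
      dec <- if (decoder == "kernel")
        kernel_decode(raster, pop, dt = dt, domain = lambda1,
                      resolution = res, plan = plan,
                      estimate_every = estimate_every)
      else
        bayes_decode(raster, pop, motion, dt = dt, domain = lambda1,
                     resolution = res, estimate_every = estimate_every)
      reports[[s]] <- global_rmse(dec, traj, burn_in = burn_in)
    }
    rep <- pool_reports(reports)
    data.frame(beta = beta, mse = rep$mse, rmse = rep$rmse,
               ci_halfwidth = rep$ci_halfwidth)
  })
  do.call(rbind, rows)
}

#' Power-law recovery experiment
#'
#' Simulates fractional-Brownian-motion trajectories, computes the MSD and
#' fits a power law over the given window; reports the distribution of
#' recovered exponents and prefactors.
#'
#' @param g,epsilon ground-truth motion parameters.
#' @param n_realizations number of independent trajectories.
#' @param duration,dt trajectory parameters (s).
#' @param window fit window (s).
#' @param seed base seed.
#' @return data frame with one row per realization (columns \code{g},
#'   \code{epsilon}, \code{r_squared}).
#' @export
run_msd_recovery <- function(g, epsilon, n_realizations = 100, duration = 30,
                             dt = 0.04, window = c(0.32, 0.8), seed = 1) {
  rows <- lapply(seq_len(n_realizations), function(s) {
    traj <- simulate_power_law(g, epsilon, dt, duration, derive_seed(seed, s))
    fit <- fit_power_law(compute_msd(traj, window[2] * 1.5), window)
    data.frame(g = fit$g, epsilon = fit$epsilon, r_squared = fit$r_squared)
  })
  do.call(rbind, rows)
}

#' Run a preset experiment from a configuration
#'
#' Dispatches to the experiment runners from a single configuration list and
#' attaches provenance (seed, configuration, package version, runtime).
#' Presets: \code{"single_module"}, \code{"allocation_comparison"},
#' \code{"beta_sweep"}, \code{"msd_recovery"}. All remaining configuration
#' entries are passed to the corresponding runner as arguments.
#'
#' @param config named list with at least \code{preset} and \code{seed};
#'   \code{n_sims} (or \code{n_realizations}) must be positive.
#' @return list with \code{reports} (runner output) and \code{provenance}.
#'   Re-running the same configuration reproduces the reports exactly.
#' @export
run_experiment <- function(config) {
  if (is.null(config$preset)) stop("config must name a `preset`")
  preset <- match.arg(config$preset,
                      c("single_module", "allocation_comparison",
                        "beta_sweep", "msd_recovery"))
  if (!is.null(config$n_sims) && config$n_sims < 1)
    stop("validation error: `n_sims` must be at least 1")
  if (!is.null(config$n_realizations) && config$n_realizations < 1)
    stop("validation error: `n_realizations` must be at least 1")
  args <- config[setdiff(names(config), "preset")]
  fun <- switch(preset,
                single_module = run_single_module,
                allocation_comparison = run_allocation_comparison,
                beta_sweep = run_beta_sweep,
                msd_recovery = run_msd_recovery)
  t0 <- proc.time()[["elapsed"]]
  reports <- do.call(fun, args)
  runtime <- proc.time()[["elapsed"]] - t0
  list(reports = reports,
       provenance = list(preset = preset, config = config,
                         seed = config$seed %||% NA,
                         package_version =
                           as.character(utils::packageVersion("gridcode")),
                         runtime_s = runtime))
}
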