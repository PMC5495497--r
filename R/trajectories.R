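# Trajectory generation (random walk, fractional Brownian motion) and
# mean-square-displacement analysis.

new_trajectory <- function(dt, xy_raw, domain = NULL, motion = NULL) {
  domain <- as_domain(domain)
  xy <- if (is.null(domain)) xy_raw else wrap_positions(xy_raw, domain)
  structure(list(dt = dt, positions = xy, positions_raw = xy_raw,
                 domain = domain, motion = motion,
                 duration = (nrow(xy_raw) - 1) * dt),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d samples, dt = %g s, duration = %g s%s\n",
              nrow(x$positions), x$dt, x$duration,
              if (is.null(x$domain)) "" else
                sprintf(", periodic domain %g x %g m", x$domain[1],
                        x$domain[2])))
  invisible(x)
}

#' @export
plot.trajectory <- function(x, ...) {
  plot(x$positions_raw[, 1], x$positions_raw[, 2], type = "l",
       xlab = "x (m)", ylab = "y (m)", asp = 1, ...)
  invisible(x)
}

#' Simulate a simple random walk
#'
#' Independent Gaussian increments per axis with variance \code{2 * D * dt}
#' each, so the 2D mean square displacement grows as \eqn{4 D \Delta t}.
#' When \code{domain_size} is given the positions are additionally wrapped
#' onto the periodic domain; raw (unwrapped) coordinates are retained for MSD
#' analysis.
#'
#' @param D diffusion coefficient (m^2/s); \code{D = 0} gives a constant
#'   position.
#' @param dt time step (s).
#' @param duration total duration (s); must exceed \code{dt}.
#' @param seed integer seed (deterministic output).
#' @param domain_size optional periodic domain: side length of a square, or a
#'   pair \code{c(Lx, Ly)}.
#' @param start starting position (defaults to the domain center, or the
#'   origin without a domain).
#' @return an object of class \code{trajectory} with positions at times
#'   \code{0, dt, ..., duration}.
#' @export
simulate_random_walk <- function(D, dt, duration, seed, domain_size = NULL,
                                 start = NULL) {
  stopifnot(D >= 0)
  stop_if_not_scalar_pos(dt, "dt")
  if (dt >= duration) stop("`dt` must be smaller than `duration`")
  domain <- as_domain(domain_size)
  n <- round(duration / dt)
  set.seed(as.integer(seed))
  inc <- matrix(rnorm(2 * n, sd = sqrt(2 * D * dt)), ncol = 2)
  start <- start %||% (if (is.null(domain)) c(0, 0) else domain / 2)
  cum <- matrix(apply(inc, 2, cumsum), ncol = 2)
  xy <- rbind(start, sweep(cum, 2, start, `+`))
  dimnames(xy) <- NULL
  new_trajectory(dt, xy, domain, motion_random_walk(D))
}

# exact fractional Gaussian noise by circulant embedding: n stationary
# increments with Var = var1 and Cor(k) of fGn with Hurst exponent H
fgn_sample <- function(n, H, var1) {
  if (n < 2) stop("need at least 2 increments")
  k <- 0:n
  gam <- var1 / 2 * ((k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
  M <- 2L * n
  r <- c(gam[1:(n + 1)], gam[n:2])
  lam <- Re(fft(r))
  lam[lam < 0 & lam > -1e-9 * max(lam)] <- 0
  if (any(lam < 0)) stop("circulant embedding failed (negative eigenvalue)")
  W <- complex(length.out = M)
  W[1] <- rnorm(1)
  W[n + 1] <- rnorm(1)
  if (n > 1) {
    a <- rnorm(n - 1)
    b <- rnorm(n - 1)
    idx <- 2:n
    W[idx] <- complex(real = a, imaginary = b) / sqrt(2)
    W[M - idx + 2] <- Conj(W[idx])
  }
  Re(fft(sqrt(lam / M) * W))[1:n]
}

#' Simulate power-law motion (fractional Brownian motion)
#'
#' Generates a trajectory whose 2D mean square displacement is exactly
#' \eqn{g \Delta t^\epsilon} at every lag: each axis is a fractional Brownian
#' motion with Hurst exponent \eqn{H = \epsilon / 2}, sampled with exact
#' covariance by circulant embedding of the increment process. At
#' \eqn{\epsilon = 1} this reduces to a simple random walk with
#' \eqn{D = g/4}.
#'
#' @param g MSD prefactor (m^2 / s^epsilon).
#' @param epsilon MSD exponent, in (0, 2).
#' @param dt time step (s).
#' @param duration total duration (s).
#' @param seed integer seed.
#' @param domain_size optional periodic domain (see
#'   \code{\link{simulate_random_walk}}).
#' @param start starting position.
#' @return an object of class \code{trajectory}.
#' @export
simulate_power_law <- function(g, epsilon, dt, duration, seed,
                               domain_size = NULL, start = NULL) {
  stop_if_not_scalar_pos(g, "g")
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0 ||
      epsilon >= 2)
    stop("`epsilon` must lie in (0, 2)")
  stop_if_not_scalar_pos(dt, "dt")
  if (dt >= duration) stop("`dt` must be smaller than `duration`")
  domain <- as_domain(domain_size)
  n <- round(duration / dt)
  set.seed(as.integer(seed))
  var1 <- (g / 2) * dt^epsilon  # per-axis single-increment variance
  incx <- fgn_sample(n, epsilon / 2, var1)
  incy <- fgn_sample(n, epsilon / 2, var1)
  start <- start %||% (if (is.null(domain)) c(0, 0) else domain / 2)
  xy <- rbind(start, cbind(start[1] + cumsum(incx), start[2] + cumsum(incy)))
  dimnames(xy) <- NULL
  new_trajectory(dt, xy, domain, motion_power_law(g, epsilon))
}

#' Empirical mean square displacement
#'
#' For each lag (multiple of the trajectory \code{dt} up to \code{max_lag})
#' averages \eqn{|x(t + \ell) - x(t)|^2} over all overlapping pairs, using
#' the raw (unwrapped) coordinates.
#'
#' @param traj a \code{trajectory}.
#' @param max_lag largest lag (s); must be below the duration.
#' @return an object of class \code{msd_curve} with fields \code{lags},
#'   \code{msd} and \code{n_pairs}.
#' @export
compute_msd <- function(traj, max_lag) {
  if (max_lag >= traj$duration) stop("`max_lag` must be below the duration")
  xy <- traj$positions_raw
  n <- nrow(xy)
  nl <- floor(max_lag / traj$dt)
  if (nl < 1) stop("`max_lag` shorter than one time step")
  msd <- numeric(nl)
  npairs <- integer(nl)
  for (l in seq_len(nl)) {
    d <- xy[(1 + l):n, , drop = FALSE] - xy[1:(n - l), , drop = FALSE]
    msd[l] <- mean(d[, 1]^2 + d[, 2]^2)
    npairs[l] <- n - l
  }
  structure(list(lags = seq_len(nl) * traj$dt, msd = msd, n_pairs = npairs),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("msd_curve: %d lags from %g to %g s\n", length(x$lags),
              x$lags[1], x$lags[length(x$lags)]))
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, ...) {
  plot(x$lags, x$msd, log = "xy", xlab = "lag (s)", ylab = "MSD (m^2)", ...)
  invisible(x)
}

#' Fit a power law to an MSD curve
#'
#' Ordinary least squares of \code{log(msd)} on \code{log(lag)} over the lags
#' inside \code{window}: the slope estimates the exponent \eqn{\epsilon}, the
#' intercept \eqn{\log g}.
#'
#' @param msd an \code{msd_curve}.
#' @param window fit window \code{c(lo, hi)} in seconds (inclusive); must
#'   contain at least 3 lags.
#' @return an object of class \code{power_law_fit} with fields \code{g},
#'   \code{epsilon}, \code{fit_window}, \code{r_squared}.
#' @export
fit_power_law <- function(msd, window = c(0.32, 0.8)) {
  sel <- msd$lags >= window[1] & msd$lags <= window[2]
  if (sum(sel) < 3) stop("fit window must contain at least 3 lags")
  if (any(msd$msd[sel] <= 0))
    stop("MSD values in the fit window must be positive")
  y <- log(msd$msd[sel])
  fit <- lm(y ~ log(msd$lags[sel]))
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(residuals(fit)^2) / ss_tot else 1
  structure(list(g = exp(unname(coef(fit)[1])),
                 epsilon = unname(coef(fit)[2]),
                 fit_window = window,
                 r_squared = r2),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "power_law_fit: MSD = %.4g * lag^%.4g (window [%g, %g] s, R^2 = %.4f)\n",
    x$g, x$epsilon, x$fit_window[1], x$fit_window[2], x$r_squared))
  invisible(x)
}

#' @export
coef.power_law_fit <- function(object, ...) {
  c(g = object$g, epsilon = object$epsilon)
}

#' Trajectory and MSD-report I/O
#'
#' Trajectories are stored as delimited text with header \code{t,x,y}
#' (seconds, meters); the reader skips comment lines starting with \code{#}.
#' \code{write_msd_report} stores an MSD curve and its power-law fit as JSON.
#'
#' @param traj a \code{trajectory}.
#' @param path file path.
#' @param dt time step override for \code{read_trajectory} (inferred from the
#'   time column when \code{NULL}).
#' @param domain_size optional periodic domain to attach on read.
#' @param msd an \code{msd_curve}.
#' @param fit a \code{power_law_fit} (optional).
#' @return \code{read_trajectory} returns a \code{trajectory}.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt=%.17g duration=%.17g", traj$dt, traj$duration),
             con)
  if (!is.null(traj$domain))
    writeLines(sprintf("# domain=%.17g,%.17g", traj$domain[1],
                       traj$domain[2]), con)
  writeLines("t,x,y", con)
  t <- (seq_len(nrow(traj$positions_raw)) - 1) * traj$dt
  write.table(data.frame(t = t, x = traj$positions_raw[, 1],
                         y = traj$positions_raw[, 2]),
              con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, dt = NULL, domain_size = NULL) {
  df <- read.table(path, sep = ",", header = TRUE, comment.char = "#")
  if (!all(c("t", "x", "y") %in% names(df)))
    stop("trajectory file must have header t,x,y")
  if (nrow(df) < 2) stop("trajectory must have at least 2 samples")
  dt <- dt %||% (df$t[2] - df$t[1])
  new_trajectory(dt, cbind(df$x, df$y), as_domain(domain_size))
}

#' @rdname write_trajectory
#' @export
write_msd_report <- function(msd, path, fit = NULL) {
  doc <- list(lags = msd$lags, msd = msd$msd, n_pairs = msd$n_pairs)
  if (!is.null(fit))
    doc$fit <- list(g = fit$g, epsilon = fit$epsilon,
                    window = fit$fit_window, r_squared = fit$r_squared)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
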