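# Position decoders: recursive Bayesian filter with diffusion prior, and the
# kernel (filtered-spike-count) decoder.

#' Posterior grid over a periodic domain
#'
#' \code{bayes_init_uniform} creates a normalized uniform posterior over a
#' periodic rectangular domain discretized at \code{resolution} meters per
#' node (which must divide the side lengths). The posterior is maintained in
#' the log domain.
#'
#' @param domain_side side of the periodic square domain (m), or a pair
#'   \code{c(Lx, Ly)}.
#' @param resolution node spacing (m).
#' @return an object of class \code{posterior_grid}: fields \code{domain},
#'   \code{resolution}, \code{log_p} (an \code{nx x ny} matrix; node centers
#'   at \code{(ix - 0.5) * resolution}) and \code{time}.
#' @export
bayes_init_uniform <- function(domain_side, resolution) {
  domain <- as_domain(domain_side)
  stop_if_not_scalar_pos(resolution, "resolution")
  nx <- domain[1] / resolution
  ny <- domain[2] / resolution
  if (abs(nx - round(nx)) > 1e-8 || abs(ny - round(ny)) > 1e-8)
    stop("`resolution` must divide the domain side lengths")
  nx <- as.integer(round(nx))
  ny <- as.integer(round(ny))
  structure(list(domain = domain, resolution = resolution,
                 log_p = matrix(-log(nx * ny), nx, ny), time = 0),
            class = "posterior_grid")
}

#' @export
print.posterior_grid <- function(x, ...) {
  cat(sprintf(
    "posterior_grid: %d x %d nodes at %g m over %g x %g m (t = %g s)\n",
    nrow(x$log_p), ncol(x$log_p), x$resolution, x$domain[1], x$domain[2],
    x$time))
  invisible(x)
}

# node center coordinates of a posterior grid, as an (nx*ny) x 2 matrix in
# column-major order (x index fastest)
grid_nodes <- function(grid) {
  nx <- nrow(grid$log_p)
  ny <- ncol(grid$log_p)
  res <- grid$resolution
  cbind(rep((seq_len(nx) - 0.5) * res, ny),
        rep((seq_len(ny) - 0.5) * res, each = nx))
}

# argmax of a posterior grid; ties broken at the lowest linear index
grid_argmax <- function(grid) {
  i <- which.max(grid$log_p)
  nodes <- grid_nodes(grid)
  nodes[i, ]
}

# per-neuron log tuning curves on the grid nodes (exact lattice sums),
# floored; columns are neurons. Reference path used by the R-level decoders.
log_rate_table <- function(pop, grid, floor_frac = 1e-12, tol = 1e-12) {
  nodes <- grid_nodes(grid)
  pa <- pop_arrays(pop)
  n <- length(pa$module)
  W <- matrix(0, nrow(nodes), n)
  for (j in seq_len(n)) {
    md <- pa$module[j] + 1L
    f <- cpp_firing_rate(nodes[, 1], nodes[, 2], pa$lambda[md], pa$theta[md],
                         pa$sigma[md], pa$rmax[md], pa$phx[j], pa$phy[j], tol)
    W[, j] <- log(pmax(f, floor_frac * pa$rmax[md]))
  }
  W
}

#' One step of the recursive Bayesian filter (reference implementation)
#'
#' Applies the dynamic update rule for one time bin: (i) diffusion — wrapped
#' convolution with an isotropic Gaussian of per-axis variance
#' \code{2 * D * dt}; (ii) observation — add
#' \eqn{\sum_\mu [k_\mu \log f_\mu(x) - f_\mu(x) dt]} in the log domain;
#' (iii) renormalization. This is the plain R reference used for validation;
#' \code{\link{bayes_decode}} runs the same recursion in compiled code.
#'
#' @param post a \code{posterior_grid}.
#' @param counts integer vector of per-neuron spike counts in this bin.
#' @param pop the \code{grid_population}.
#' @param motion a \code{\link{motion_random_walk}} (the filter's transition
#'   kernel is diffusive).
#' @param dt bin width (s).
#' @param diffuse apply the diffusion step (skipped for the first bin, whose
#'   prior already refers to the current time).
#' @param floor_frac relative floor for log tuning curves.
#' @return the updated \code{posterior_grid}.
#' @export
bayes_step <- function(post, counts, pop, motion, dt, diffuse = TRUE,
                       floor_frac = 1e-12) {
  if (!inherits(motion, "motion_model") || motion$kind != "random_walk")
    stop("the Bayesian filter requires random-walk motion")
  if (length(counts) != pop$total_n)
    stop("`counts` must have one entry per neuron")
  lp <- post$log_p
  if (diffuse && motion$D > 0) {
    w <- gauss_kernel_r(sqrt(2 * motion$D * dt), post$resolution)
    mx <- max(lp)
    if (!is.finite(mx))
      stop("posterior underflow: all probability mass lost; use a coarser time step or finer grid resolution")
    p <- exp(lp - mx)
    p <- conv_wrap_mat(conv_wrap_mat(p, w, along = 1), w, along = 2)
    lp <- log(p)
  }
  W <- log_rate_table(pop, post, floor_frac = floor_frac)
  f <- exp(W)
  obs <- as.vector(W %*% counts - rowSums(f) * dt)
  lp <- lp + matrix(obs, nrow(lp), ncol(lp))
  z <- logsumexp(as.vector(lp))
  if (!is.finite(z))
    stop("posterior underflow: all probability mass lost; use a coarser time step or finer grid resolution")
  post$log_p <- lp - z
  post$time <- post$time + dt
  post
}

# decoder lookup tables: per-module log-rate templates on the lattice unit
# cell plus the population-summed rate on the decoding grid
make_decoder_tables <- function(pop, nx, ny, res, template_n = 256,
                                tol = 1e-12, floor_frac = 1e-12) {
  pa <- pop_arrays(pop)
  m <- length(pa$lambda)
  nt <- as.integer(template_n)
  logT <- matrix(0, nt * nt, m)
  total <- numeric(nx * ny)
  for (i in seq_len(m)) {
    Tm <- cpp_cell_template(nt, pa$lambda[i], pa$sigma[i], pa$rmax[i], tol)
    logT[, i] <- as.vector(log(pmax(Tm, floor_frac * pa$rmax[i])))
    # population-summed rate of the module: splat the cell phases onto the
    # unit-cell grid and circularly convolve with the rate template
    sel <- pa$module == (i - 1L)
    uv <- lattice_coords(cbind(pa$phx[sel], pa$phy[sel]), pa$lambda[i],
                         pa$theta[i])
    gu <- (uv[, 1] %% 1) * nt
    gv <- (uv[, 2] %% 1) * nt
    i0 <- floor(gu); fu <- gu - i0; i0 <- i0 %% nt
    j0 <- floor(gv); fv <- gv - j0; j0 <- j0 %% nt
    i1 <- (i0 + 1) %% nt
    j1 <- (j0 + 1) %% nt
    S <- numeric(nt * nt)
    acc <- function(S, ii, jj, w) {
      idx <- ii + nt * jj + 1
      a <- rowsum(w, group = idx)
      at <- as.integer(rownames(a))
      S[at] <- S[at] + a[, 1]
      S
    }
    S <- acc(S, i0, j0, (1 - fu) * (1 - fv))
    S <- acc(S, i1, j0, fu * (1 - fv))
    S <- acc(S, i0, j1, (1 - fu) * fv)
    S <- acc(S, i1, j1, fu * fv)
    Sm <- matrix(S, nt, nt)
    conv <- Re(fft(fft(Sm) * fft(Tm), inverse = TRUE)) / (nt * nt)
    total <- total + cpp_sample_cell_map(conv, nx, ny, res, pa$lambda[i],
                                         pa$theta[i])
  }
  list(logT = logT, nt = nt, total_rate = pmax(total, 0), pa = pa)
}

# shared front-end for the compiled decoders
decode_geometry <- function(pop, domain, resolution) {
  domain <- as_domain(domain)
  sig_min <- min(vapply(pop$modules, `[[`, 1, "sigma"))
  # default: the coarsest grid at or below sigma_min/3 that divides the
  # first domain side (square domains always work; rectangles may need an
  # explicit resolution)
  resolution <- resolution %||%
    (domain[1] / ceiling(domain[1] / (sig_min / 3)))
  if (resolution > sig_min / 3 + 1e-12)
    stop(sprintf(
      "`resolution` (%g m) too coarse: must be at most sigma_min/3 = %g m",
      resolution, sig_min / 3))
  nx <- as.integer(round(domain[1] / resolution))
  ny <- as.integer(round(domain[2] / resolution))
  if (abs(nx * resolution - domain[1]) > 1e-8 ||
      abs(ny * resolution - domain[2]) > 1e-8)
    stop("`resolution` must divide the domain side lengths")
  list(domain = domain, res = resolution, nx = nx, ny = ny)
}

truth_vectors <- function(truth, nbins, domain) {
  if (is.null(truth)) return(list(x = numeric(0), y = numeric(0)))
  xy <- if (inherits(truth, "trajectory")) truth$positions else
    matrix(truth, ncol = 2)
  if (nrow(xy) < nbins) stop("`truth` shorter than the spike raster")
  xy <- wrap_positions(xy[seq_len(nbins), , drop = FALSE], domain)
  list(x = xy[, 1], y = xy[, 2])
}

new_decode_result <- function(cpp_out, dt, geom, method, params) {
  est <- wrap_positions(cbind(cpp_out$est_x, cpp_out$est_y), geom$domain)
  structure(list(times = cpp_out$bin * dt, estimates = est,
                 local_err2 = cpp_out$local_err2,
                 n_peaks = cpp_out$n_peaks,
                 log_posterior = cpp_out$log_posterior,
                 domain = geom$domain, resolution = geom$res, dt = dt,
                 method = method, params = params),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf(
    "decode_result (%s): %d estimates, dt = %g s, grid %g m on %g x %g m\n",
    x$method, nrow(x$estimates), x$dt, x$resolution, x$domain[1],
    x$domain[2]))
  invisible(x)
}

#' Optimal Bayesian position decoding
#'
#' Runs the recursive Bayesian filter over all time bins: diffusion of the
#' posterior with the random-walk transition kernel, followed by the Poisson
#' observation update from the binned spike counts, with the maximum a
#' posteriori (argmax) position recorded per bin. The posterior lives on a
#' periodic rectangular grid; tuning curves are evaluated through per-module
#' unit-cell templates (bilinear interpolation at 1/\code{template_n} of a
#' spacing).
#'
#' @param raster a \code{spike_raster}.
#' @param pop the \code{grid_population} that generated the spikes.
#' @param motion a \code{\link{motion_random_walk}} (sets the diffusion
#'   prior; use \code{D = 0} for a static variable).
#' @param dt decoding bin width (s).
#' @param domain periodic domain: side of a square (m) or \code{c(Lx, Ly)}.
#' @param resolution grid resolution (m); default: the coarsest grid at or
#'   below \code{sigma_min/3} that divides the domain side; must not exceed
#'   \code{sigma_min/3}.
#' @param truth optional \code{trajectory} (or matrix of positions, one per
#'   bin): when given, the per-bin local error (squared toroidal distance
#'   from the truth to the nearest posterior peak) is recorded.
#' @param estimate_every record estimates every this many bins (the last bin
#'   of each block).
#' @param refine use quadratic (3-point) sub-grid interpolation of peak
#'   positions; set \code{FALSE} to report raw node centers.
#' @param prior optional \code{posterior_grid} prior (default uniform).
#' @param peak_rel_tol posterior peaks below this fraction of the maximum are
#'   ignored by the local-error metric.
#' @param keep_posterior return the final normalized log posterior.
#' @param template_n tuning-curve template resolution per unit cell.
#' @return an object of class \code{decode_result} with per-bin \code{times}
#'   and \code{estimates} (and \code{local_err2} when \code{truth} given).
#' @export
bayes_decode <- function(raster, pop, motion, dt = 1e-3, domain,
                         resolution = NULL, truth = NULL, estimate_every = 1,
                         refine = TRUE, prior = NULL, peak_rel_tol = 1e-3,
                         keep_posterior = FALSE, template_n = 256) {
  if (!inherits(motion, "motion_model") || motion$kind != "random_walk")
    stop("the Bayesian filter requires random-walk motion")
  geom <- decode_geometry(pop, domain, resolution)
  nbins <- max(1, round(raster$duration / dt))
  counts <- bin_spikes(raster, dt, n_bins = nbins)
  tab <- make_decoder_tables(pop, geom$nx, geom$ny, geom$res,
                             template_n = template_n)
  tr <- truth_vectors(truth, nbins, geom$domain)
  log_prior <- if (is.null(prior)) rep(-log(geom$nx * geom$ny),
                                       geom$nx * geom$ny)
               else as.vector(prior$log_p)
  out <- cpp_bayes_decode(geom$nx, geom$ny, geom$res, log_prior, counts$bin,
                          counts$neuron, counts$count, nbins, dt, motion$D,
                          tab$logT, tab$nt, tab$pa$lambda, tab$pa$theta,
                          tab$pa$module, tab$pa$phx, tab$pa$phy,
                          tab$total_rate, as.integer(estimate_every), tr$x,
                          tr$y, log(peak_rel_tol), refine, keep_posterior)
  new_decode_result(out, dt, geom, "bayes",
                    list(D = motion$D, resolution = geom$res,
                         estimate_every = estimate_every, refine = refine))
}

#' Kernel decoder log posterior at one time (reference implementation)
#'
#' Direct evaluation of the filtered-spike-count readout: each module's
#' spikes are filtered by its causal kernel \eqn{h_i} and weighted by the log
#' tuning curves, \eqn{\log p(x; t) \propto \sum_\mu \ln f_\mu(x) \sum_{t'
#' \le t} h_i(t - t')}. Used for validation; \code{\link{kernel_decode}} runs
#' the same computation recursively in compiled code.
#'
#' @param raster a \code{spike_raster}.
#' @param pop the \code{grid_population}.
#' @param kernels list with \code{shape} ("exponential" or "rectangular") and
#'   \code{tau} (per-module time constants / widths, s).
#' @param t evaluation time (s).
#' @param grid a \code{posterior_grid} supplying the geometry.
#' @param floor_frac relative floor for log tuning curves.
#' @return a \code{posterior_grid} with the normalized log posterior.
#' @export
kernel_log_posterior <- function(raster, pop, kernels, t, grid,
                                 floor_frac = 1e-12) {
  stopifnot(all(kernels$tau > 0))
  shape <- match.arg(kernels$shape, c("exponential", "rectangular"))
  pa <- pop_arrays(pop)
  W <- log_rate_table(pop, grid, floor_frac = floor_frac)
  s <- numeric(pop$total_n)
  for (n in seq_len(pop$total_n)) {
    ts <- raster$times[[n]]
    ts <- ts[ts <= t]
    if (length(ts) == 0) next
    tau_i <- kernels$tau[pa$module[n] + 1L]
    s[n] <- if (shape == "exponential") sum(exp(-(t - ts) / tau_i))
            else sum((t - ts) < tau_i)
  }
  lp <- as.vector(W %*% s)
  grid$log_p <- matrix(lp - logsumexp(lp), nrow(grid$log_p),
                       ncol(grid$log_p))
  grid$time <- t
  grid
}

#' Kernel (filtered-spike-count) position decoding
#'
#' Near-optimal readout: spikes of module \eqn{i} are filtered by a causal
#' kernel with module-specific time constant \eqn{\tau_i} and weighted by the
#' log tuning curves; the estimate is the argmax over positions. With
#' exponential kernels the filtered counts are updated recursively; with
#' rectangular kernels spikes expire after the window width.
#'
#' @inheritParams bayes_decode
#' @param plan a \code{module_plan} supplying per-module time constants
#'   (\code{plan$taus}); alternatively pass \code{taus} directly.
#' @param taus per-module kernel time constants (s), overriding the plan.
#' @param shape kernel shape.
#' @return an object of class \code{decode_result}.
#' @export
kernel_decode <- function(raster, pop, plan = NULL, dt = 1e-3, domain,
                          resolution = NULL, taus = NULL,
                          shape = c("exponential", "rectangular"),
                          truth = NULL, estimate_every = 1, refine = TRUE,
                          peak_rel_tol = 1e-3, template_n = 256) {
  shape <- match.arg(shape)
  taus <- taus %||% plan$taus
  if (is.null(taus)) stop("supply `plan` (with taus) or `taus`")
  if (length(taus) == 1) taus <- rep(taus, length(pop$modules))
  if (length(taus) != length(pop$modules))
    stop("`taus` must have one entry per module")
  stopifnot(all(taus > 0))
  geom <- decode_geometry(pop, domain, resolution)
  nbins <- max(1, round(raster$duration / dt))
  counts <- bin_spikes(raster, dt, n_bins = nbins)
  tab <- make_decoder_tables(pop, geom$nx, geom$ny, geom$res,
                             template_n = template_n)
  tr <- truth_vectors(truth, nbins, geom$domain)
  out <- cpp_kernel_decode(geom$nx, geom$ny, geom$res, counts$bin,
                           counts$neuron, counts$count, nbins, dt, tab$logT,
                           tab$nt, tab$pa$lambda, tab$pa$theta, tab$pa$module,
                           tab$pa$phx, tab$pa$phy, taus,
                           if (shape == "exponential") 0L else 1L,
                           as.integer(estimate_every), tr$x, tr$y,
                           log(peak_rel_tol), refine)
  new_decode_result(out, dt, geom, paste0("kernel_", shape),
                    list(taus = taus, shape = shape, resolution = geom$res,
                         estimate_every = estimate_every, refine = refine))
}

#' Readout weight table
#'
#' Synaptic weights of a readout (place-cell-like) network implementing the
#' kernel decoder: \code{weight[p, mu] = ln f_mu(x_p)}, clipped at a floor.
#' Combining these weights with exponentially filtered spike counts and
#' taking the argmax reproduces \code{\link{kernel_decode}}.
#'
#' @param pop a \code{grid_population}.
#' @param positions matrix (k x 2) of readout positions (m).
#' @param floor_frac the floor is \code{log(floor_frac * rmax)} per neuron.
#' @return a k x total_n weight matrix.
#' @export
build_readout_weights <- function(pop, positions, floor_frac = 1e-12) {
  positions <- matrix(as.numeric(positions), ncol = 2)
  pa <- pop_arrays(pop)
  n <- length(pa$module)
  W <- matrix(0, nrow(positions), n)
  for (j in seq_len(n)) {
    md <- pa$module[j] + 1L
    f <- cpp_firing_rate(positions[, 1], positions[, 2], pa$lambda[md],
                         pa$theta[md], pa$sigma[md], pa$rmax[md], pa$phx[j],
                         pa$phy[j], 1e-12)
    W[, j] <- log(pmax(f, floor_frac * pa$rmax[md]))
  }
  W
}
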