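# Grid-cell tuning curves on a triangular lattice and their Fisher
# information properties.

# lattice basis for spacing lambda, orientation theta:
# b1 = lambda*R(theta)*(1,0), b2 = lambda*R(theta)*(1/2, sqrt(3)/2)
lattice_basis <- function(lambda, theta) {
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  rot %*% (lambda * matrix(c(1, 0, 0.5, sqrt(3) / 2), 2, 2))
}

# lattice coordinates (coefficients in the module basis) of points (n x 2)
lattice_coords <- function(points, lambda, theta) {
  B <- lattice_basis(lambda, theta)
  t(solve(B, t(points)))
}

#' Specify one grid module
#'
#' A module is a set of cells sharing a triangular firing-field lattice with
#' spacing \code{spacing} and a common orientation; individual cells differ
#' only by their spatial phase (a 2D offset inside the lattice unit cell).
#' The tuning curve of a cell is a sum of Gaussians of width \code{sigma}
#' (default \code{spacing/10}) and peak rate \code{rmax}, placed at every
#' lattice point.
#'
#' @param index module index (1 = largest spacing).
#' @param spacing grid spacing lambda in meters.
#' @param orientation lattice orientation in radians.
#' @param n_cells number of cells in the module.
#' @param phases optional \code{n_cells x 2} matrix of phases (meters); each
#'   phase must lie inside the fundamental unit cell. If \code{NULL}, phases
#'   must be supplied later (e.g. by \code{\link{build_population}}).
#' @param sigma_over_lambda tuning width as a fraction of the spacing.
#' @param rmax maximal firing rate in Hz.
#' @return an object of class \code{grid_module}.
#' @export
grid_module <- function(index, spacing, orientation, n_cells, phases = NULL,
                        sigma_over_lambda = 0.1, rmax = 10) {
  stop_if_not_scalar_pos(spacing, "spacing")
  stop_if_not_scalar_pos(rmax, "rmax")
  stop_if_not_scalar_pos(sigma_over_lambda, "sigma_over_lambda")
  if (!is.numeric(n_cells) || length(n_cells) != 1 || n_cells < 1 ||
      n_cells != round(n_cells))
    stop("`n_cells` must be a positive integer")
  if (!is.null(phases)) {
    phases <- matrix(as.numeric(phases), ncol = 2)
    if (nrow(phases) != n_cells)
      stop("`phases` must have one row per cell")
    lc <- lattice_coords(phases, spacing, orientation)
    if (any(lc < -1e-9) || any(lc >= 1 + 1e-9))
      stop("every phase must lie inside the fundamental unit cell")
  }
  structure(list(index = as.integer(index), spacing = spacing,
                 orientation = orientation, n_cells = as.integer(n_cells),
                 sigma = spacing * sigma_over_lambda, rmax = rmax,
                 phases = phases),
            class = "grid_module")
}

#' Construct a grid-cell population directly from spacings and counts
#'
#' @param spacings vector of module spacings (meters), strictly decreasing.
#' @param counts vector of per-module cell counts (positive integers).
#' @param seed integer seed for the random orientations and phases.
#' @param orientations optional vector of per-module orientations (radians);
#'   drawn uniformly at random when \code{NULL}.
#' @param sigma_over_lambda,rmax tuning-curve parameters, see
#'   \code{\link{grid_module}}.
#' @return an object of class \code{grid_population}.
#' @seealso \code{\link{build_population}} to realize an optimizer plan.
#' @export
grid_population <- function(spacings, counts, seed, orientations = NULL,
                            sigma_over_lambda = 0.1, rmax = 10) {
  m <- length(spacings)
  if (length(counts) != m) stop("`spacings` and `counts` lengths differ")
  if (m > 1 && any(diff(spacings) >= 0))
    stop("module spacings must be strictly decreasing")
  if (any(counts < 1) || any(counts != round(counts)))
    stop("invalid plan: all module cell counts must be integers >= 1")
  set.seed(as.integer(seed))
  modules <- vector("list", m)
  for (i in seq_len(m)) {
    theta <- if (is.null(orientations)) runif(1, 0, 2 * pi) else orientations[i]
    B <- lattice_basis(spacings[i], theta)
    uv <- cbind(runif(counts[i]), runif(counts[i]))
    phases <- t(B %*% t(uv))
    modules[[i]] <- grid_module(i, spacings[i], theta, counts[i],
                                phases = phases,
                                sigma_over_lambda = sigma_over_lambda,
                                rmax = rmax)
  }
  structure(list(modules = modules, total_n = as.integer(sum(counts)),
                 rng_seed = as.integer(seed)),
            class = "grid_population")
}

#' Realize a module plan as a concrete population
#'
#' Draws one uniformly random lattice orientation per module and one
#' uniformly random phase (over the rhombic unit cell) per cell, then
#' packages the result as a \code{grid_population}. Deterministic given
#' \code{seed}.
#'
#' @param plan a \code{\link{module_plan}} from \code{\link{allocate_modules}}.
#' @param seed integer seed.
#' @param sigma_over_lambda,rmax tuning-curve parameters.
#' @return an object of class \code{grid_population}.
#' @export
build_population <- function(plan, seed, sigma_over_lambda = 0.1,
                             rmax = plan$params$rmax %||% 10) {
  if (!inherits(plan, "module_plan")) stop("`plan` must be a module_plan")
  grid_population(plan$lambdas, plan$n, seed,
                  sigma_over_lambda = sigma_over_lambda, rmax = rmax)
}

#' @export
print.grid_population <- function(x, ...) {
  cat(sprintf("grid_population: %d modules, %d cells (seed %d)\n",
              length(x$modules), x$total_n, x$rng_seed))
  df <- data.frame(module = vapply(x$modules, `[[`, 1L, "index"),
                   spacing_m = vapply(x$modules, `[[`, 1, "spacing"),
                   cells = vapply(x$modules, `[[`, 1L, "n_cells"),
                   orientation_rad = round(
                     vapply(x$modules, `[[`, 1, "orientation"), 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.grid_module <- function(x, ...) {
  cat(sprintf(
    "grid_module %d: spacing %.4g m, %d cells, sigma %.4g m, rmax %g Hz\n",
    x$index, x$spacing, x$n_cells, x$sigma, x$rmax))
  invisible(x)
}

#' Tuning-curve firing rate of one grid cell
#'
#' Evaluates \eqn{f(x) = \sum_k r_{max} \exp(-|x - c_k|^2 / (2\sigma^2))}
#' where the field centers \eqn{c_k} form the module's triangular lattice
#' shifted by the cell's phase. The lattice sum is truncated where a term's
#' relative contribution falls below \code{tol}.
#'
#' @param module a \code{\link{grid_module}}.
#' @param phase_offset the cell's phase, a 2D offset in meters.
#' @param position a 2D point or an \code{n x 2} matrix of points (meters).
#' @param tol relative truncation tolerance for the lattice sum.
#' @return firing rate(s) in Hz.
#' @export
firing_rate <- function(module, phase_offset, position, tol = 1e-12) {
  position <- matrix(as.numeric(position), ncol = 2)
  if (any(!is.finite(position))) stop("`position` must be finite")
  cpp_firing_rate(position[, 1], position[, 2], module$spacing,
                  module$orientation, module$sigma, module$rmax,
                  phase_offset[1], phase_offset[2], tol)
}

# summed firing rate of all cells of a population at given positions
population_rate <- function(pop, position, tol = 1e-12) {
  position <- matrix(as.numeric(position), ncol = 2)
  total <- numeric(nrow(position))
  for (mod in pop$modules)
    for (i in seq_len(mod$n_cells))
      total <- total + firing_rate(mod, mod$phases[i, ], position, tol)
  total
}

#' Fisher information constant of periodic Gaussian tuning curves
#'
#' For a module of \code{n} cells with spacing \code{lambda} whose phases
#' cover the unit cell densely and uniformly, the Fisher information rate per
#' spatial direction is \eqn{J = \alpha n / \lambda^2}. For Gaussian fields
#' that are narrow relative to the spacing (\code{sigma_over_lambda} up to
#' about 0.15) the constant has the closed form
#' \eqn{\alpha = 4 \pi r_{max} / \sqrt{3}}, independent of both
#' \eqn{\lambda} and \eqn{\sigma/\lambda}: the phase average of the Poisson
#' Fisher integrand \eqn{(\partial_x f)^2 / f} over the unit cell reduces to
#' \eqn{r_{max}/(\sigma^2)} times the Gaussian normalization over the cell
#' area \eqn{\sqrt{3}\lambda^2/2}, and the \eqn{\sigma} factors cancel.
#'
#' @param r_max maximal firing rate (Hz).
#' @param sigma_over_lambda tuning width as a fraction of the spacing.
#' @param method \code{"closed_form"} (default) or \code{"quadrature"}, which
#'   integrates the Fisher integrand numerically over one unit cell (the
#'   phase average equals the spatial average over the cell).
#' @param n_grid quadrature nodes per axis when \code{method = "quadrature"}.
#' @return alpha in 1/s, such that \eqn{J = \alpha n / \lambda^2}.
#' @export
alpha_gaussian <- function(r_max = 10, sigma_over_lambda = 0.1,
                           method = c("closed_form", "quadrature"),
                           n_grid = 300) {
  stop_if_not_scalar_pos(r_max, "r_max")
  stop_if_not_scalar_pos(sigma_over_lambda, "sigma_over_lambda")
  method <- match.arg(method)
  if (method == "closed_form") return(4 * pi * r_max / sqrt(3))
  # quadrature over one unit cell (lambda = 1 WLOG; alpha is scale free)
  lambda <- 1
  sigma <- sigma_over_lambda * lambda
  mod <- grid_module(1, lambda, 0, 1, phases = matrix(0, 1, 2),
                     sigma_over_lambda = sigma_over_lambda, rmax = r_max)
  u <- (seq_len(n_grid) - 0.5) / n_grid
  B <- lattice_basis(lambda, 0)
  uv <- as.matrix(expand.grid(u = u, v = u))
  pts <- uv %*% t(B)
  h <- 1e-5 * sigma
  f0 <- firing_rate(mod, c(0, 0), pts)
  fp <- firing_rate(mod, c(0, 0), cbind(pts[, 1] + h, pts[, 2]))
  fm <- firing_rate(mod, c(0, 0), cbind(pts[, 1] - h, pts[, 2]))
  dfx <- (fp - fm) / (2 * h)
  integrand <- ifelse(f0 > 1e-280, dfx^2 / f0, 0)
  # mean over the cell times cell count density: J_cell = <(df/dx)^2/f>
  mean(integrand) * lambda^2
}

#' Fisher information rate of a module
#'
#' @param module a \code{\link{grid_module}}.
#' @param alpha the tuning-curve constant from \code{\link{alpha_gaussian}}.
#' @return \eqn{J = \alpha n / \lambda^2} in 1/(m^2 s), the Fisher
#'   information accrual rate per spatial direction.
#' @export
fisher_rate <- function(module, alpha) {
  stop_if_not_scalar_pos(alpha, "alpha")
  alpha * module$n_cells / module$spacing^2
}

#' Write / read a population as JSON
#'
#' Serializes module parameters and per-cell phases; the round trip
#' reproduces the population deterministically.
#'
#' @param pop a \code{grid_population}.
#' @param path file path.
#' @return \code{read_population} returns a \code{grid_population};
#'   \code{write_population} returns \code{path} invisibly.
#' @export
write_population <- function(pop, path) {
  doc <- list(
    total_n = pop$total_n, rng_seed = pop$rng_seed,
    modules = lapply(pop$modules, function(m)
      list(index = m$index, spacing = m$spacing, orientation = m$orientation,
           n_cells = m$n_cells, sigma = m$sigma, rmax = m$rmax,
           phases = unname(m$phases))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  modules <- lapply(seq_len(nrow(doc$modules)), function(i) {
    r <- doc$modules[i, ]
    grid_module(r$index, r$spacing, r$orientation, r$n_cells,
                phases = matrix(r$phases[[1]], ncol = 2),
                sigma_over_lambda = r$sigma / r$spacing, rmax = r$rmax)
  })
  structure(list(modules = modules, total_n = as.integer(doc$total_n),
                 rng_seed = as.integer(doc$rng_seed)),
            class = "grid_population")
}
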