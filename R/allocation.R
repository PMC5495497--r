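# Closed-form coding theory and the module allocation optimizer.

#' Motion models
#'
#' A motion model describes the statistics of the trajectory to be encoded:
#' either a simple random walk with diffusion coefficient \code{D} (2D mean
#' square displacement \eqn{4 D \Delta t}) or power-law motion with
#' \eqn{MSD = g \Delta t^\epsilon}.
#'
#' @param D diffusion coefficient (m^2/s); \code{D = 0} describes a static
#'   variable.
#' @param g power-law prefactor (m^2 / s^epsilon).
#' @param epsilon power-law exponent in (0, 2]; \code{epsilon = 1} is
#'   diffusive, \code{epsilon = 2} ballistic (constant velocity).
#' @return an object of class \code{motion_model}.
#' @export
motion_random_walk <- function(D) {
  if (!is.numeric(D) || length(D) != 1 || !is.finite(D) || D < 0)
    stop("`D` must be a non-negative finite scalar")
  structure(list(kind = "random_walk", D = D, g = 4 * D, epsilon = 1),
            class = "motion_model")
}

#' @rdname motion_random_walk
#' @export
motion_power_law <- function(g, epsilon) {
  stop_if_not_scalar_pos(g, "g")
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0 ||
      epsilon > 2)
    stop("`epsilon` must lie in (0, 2]")
  structure(list(kind = "power_law", g = g, epsilon = epsilon),
            class = "motion_model")
}

#' @export
print.motion_model <- function(x, ...) {
  if (x$kind == "random_walk")
    cat(sprintf("motion_model: random walk, D = %g m^2/s\n", x$D))
  else
    cat(sprintf("motion_model: power law, g = %g, epsilon = %g\n",
                x$g, x$epsilon))
  invisible(x)
}

#' Local mean square error laws
#'
#' Closed-form local decoding error (per the two spatial directions combined)
#' of a module with Fisher information rate \code{J}:
#' \itemize{
#'   \item static variable observed for a window \code{delta_T}:
#'     \eqn{\Delta^2 = 2 / (J \Delta T)};
#'   \item random walk with diffusion coefficient \code{D}:
#'     \eqn{\Delta^2 = 2 \sqrt{2 D / J}}, the steady state of the
#'     information-accrual / diffusion balance;
#'   \item power-law motion (\eqn{MSD = g \Delta t^\epsilon}): the optimum of
#'     the exponential-kernel error curve,
#'     \eqn{\Delta^2 = \frac{\epsilon+1}{\epsilon}
#'       \left(\frac{g \epsilon \Gamma(\epsilon+1)}{2}\right)^{1/(\epsilon+1)}
#'       J^{-\epsilon/(\epsilon+1)}}, which reduces to the random-walk law at
#'     \eqn{\epsilon = 1}, \eqn{g = 4D}.
#' }
#'
#' @param J Fisher information rate (1/(m^2 s)).
#' @param delta_T observation window (s).
#' @param D diffusion coefficient (m^2/s).
#' @param g,epsilon power-law motion parameters.
#' @return mean square error in m^2.
#' @export
local_mse_static <- function(J, delta_T) {
  stopifnot(all(J > 0), all(delta_T > 0))
  2 / (J * delta_T)
}

#' @rdname local_mse_static
#' @export
local_mse_dynamic <- function(J, D) {
  stopifnot(all(J > 0), all(D >= 0))
  2 * sqrt(2 * D / J)
}

#' @rdname local_mse_static
#' @export
local_mse_power_law <- function(J, g, epsilon) {
  stopifnot(all(J > 0), all(g > 0), epsilon > 0, epsilon <= 2)
  ((epsilon + 1) / epsilon) *
    (g * epsilon * gamma(epsilon + 1) / 2)^(1 / (epsilon + 1)) *
    J^(-epsilon / (epsilon + 1))
}

#' Theoretical error of the kernel decoder as a function of its time constant
#'
#' Local mean square error of a decoder that reads out spikes filtered by a
#' causal temporal kernel, as a function of the kernel time constant, for a
#' module with Fisher rate \code{J} under the given motion statistics:
#' \itemize{
#'   \item exponential kernel \eqn{h(t) = e^{-t/\tau}}:
#'     \eqn{V(\tau) = 1/(J\tau) + (g/2)\Gamma(\epsilon+1)\tau^\epsilon}
#'     (random walk: \eqn{1/(J\tau) + 2 D \tau});
#'   \item rectangular kernel of width \eqn{T}:
#'     \eqn{V(T) = 2/(J T) + g T^\epsilon / (\epsilon + 2)}
#'     (random walk: \eqn{2/(J T) + 4 D T / 3}).
#' }
#' The first term is estimation noise (effective observation window), the
#' second is drift of the true position over the kernel memory.
#'
#' @param J Fisher information rate (1/(m^2 s)).
#' @param tau kernel time constant (exponential) or width (rectangular), s.
#' @param motion a \code{\link{motion_random_walk}} or
#'   \code{\link{motion_power_law}} object.
#' @param shape kernel shape.
#' @return mean square error in m^2 (vectorized over \code{tau}).
#' @export
kernel_mse_theory <- function(J, tau, motion,
                              shape = c("exponential", "rectangular")) {
  shape <- match.arg(shape)
  stopifnot(all(J > 0), all(tau > 0))
  g <- motion$g
  eps <- motion$epsilon
  if (shape == "exponential")
    1 / (J * tau) + (g / 2) * gamma(eps + 1) * tau^eps
  else
    2 / (J * tau) + g * tau^eps / (eps + 2)
}

#' Optimal readout time constant
#'
#' The kernel time constant minimizing \code{\link{kernel_mse_theory}}:
#' exponential kernel \eqn{\tau^* = (2 D J)^{-1/2}} for a random walk and
#' \eqn{\tau^* = (2 / (J g \epsilon \Gamma(\epsilon+1)))^{1/(\epsilon+1)}}
#' for power-law motion; rectangular kernel
#' \eqn{T^* = (2(\epsilon+2) / (J g \epsilon))^{1/(\epsilon+1)}}
#' (\eqn{\sqrt{3/(2 D J)}} for a random walk).
#'
#' @inheritParams kernel_mse_theory
#' @return optimal time constant in seconds (vectorized over \code{J}).
#' @export
optimal_tau <- function(J, motion, shape = c("exponential", "rectangular")) {
  shape <- match.arg(shape)
  stopifnot(all(J > 0))
  g <- motion$g
  eps <- motion$epsilon
  if (shape == "exponential")
    (2 / (J * g * eps * gamma(eps + 1)))^(1 / (eps + 1))
  else
    (2 * (eps + 2) / (J * g * eps))^(1 / (eps + 1))
}

#' Closed-form asymptotic module ratios
#'
#' For motion with MSD exponent \code{epsilon}, optimal allocation gives
#' successive-module population ratio \eqn{(\epsilon+1)/\epsilon}
#' (\code{population_ratio}) and, among the small-spacing modules, spacing
#' ratio \eqn{((\epsilon+1)/\epsilon)^{\epsilon/2}}
#' (\code{spacing_ratio_limit}).
#'
#' @param epsilon MSD exponent in (0, 2].
#' @return dimensionless ratio.
#' @export
population_ratio <- function(epsilon) {
  stopifnot(epsilon > 0)
  (epsilon + 1) / epsilon
}

#' @rdname population_ratio
#' @export
spacing_ratio_limit <- function(epsilon) {
  population_ratio(epsilon)^(epsilon / 2)
}

#' Allocate neurons and spacings across modules
#'
#' Distributes \code{N} neurons over \code{m} modules and chooses the grid
#' spacings to minimize the decoding error of the nested code, for a given
#' motion statistic. Module population sizes follow an exact geometric
#' progression with ratio \eqn{(\epsilon+1)/\epsilon} (2 for a random walk),
#' normalized to sum to \code{N} and rounded to integers by largest
#' remainder. Spacings follow the chain \eqn{\lambda_{i+1} = \Delta_i /
#' \beta} anchored at \code{lambda1}, where \eqn{\Delta_i} is the
#' motion-appropriate local RMSE of module \eqn{i} evaluated at the exact
#' (fractional) geometric population sizes; this enforces the nesting
#' condition \eqn{\Delta_i = \beta \lambda_{i+1}} and reproduces the
#' closed-form spacing-ratio chain, whose asymptote is
#' \code{\link{spacing_ratio_limit}}.
#'
#' @param N total number of neurons.
#' @param m number of modules.
#' @param lambda1 largest grid spacing (m).
#' @param beta nesting safety ratio: local RMSE of module \eqn{i} equals
#'   \code{beta} times the spacing of module \eqn{i+1}.
#' @param motion a \code{motion_model}.
#' @param alpha tuning-curve Fisher constant; defaults to
#'   \code{\link{alpha_gaussian}(rmax, sigma_over_lambda)}.
#' @param rmax,sigma_over_lambda tuning-curve parameters used for the default
#'   \code{alpha} and recorded in the plan.
#' @return an object of class \code{module_plan} with per-module integer
#'   counts \code{n}, spacings \code{lambdas}, Fisher rates \code{J},
#'   predicted local RMSEs \code{deltas} and readout constants \code{taus}.
#' @export
allocate_modules <- function(N, m, lambda1, beta, motion, alpha = NULL,
                             rmax = 10, sigma_over_lambda = 0.1) {
  stop_if_not_scalar_pos(lambda1, "lambda1")
  stop_if_not_scalar_pos(beta, "beta")
  if (!inherits(motion, "motion_model")) stop("`motion` must be a motion_model")
  if (N < m || m < 1) stop("need N >= m >= 1")
  alpha <- alpha %||% alpha_gaussian(rmax, sigma_over_lambda)
  eps <- motion$epsilon
  g <- motion$g
  ratio <- population_ratio(eps)

  # exact geometric population fractions, then integer rounding
  w <- ratio^(seq_len(m))
  n_exact <- N * w / sum(w)
  n <- largest_remainder(n_exact, N)
  if (any(n < 1)) {
    feasible <- max_modules(N, ratio)
    stop(sprintf(
      "infeasible plan: a module would receive < 1 neuron; at N = %d and population ratio %.4g the maximum feasible number of modules is %d",
      as.integer(N), ratio, feasible))
  }

  # spacing chain lambda_{i+1} = Delta_i / beta with Delta from the exact
  # geometric sizes (the closed-form chain), then per-module quantities from
  # the integer counts
  lambdas <- numeric(m)
  lambdas[1] <- lambda1
  for (i in seq_len(m)) {
    J_i <- alpha * n_exact[i] / lambdas[i]^2
    d2 <- local_mse_power_law(J_i, g, eps)
    if (i < m) lambdas[i + 1] <- sqrt(d2) / beta
  }
  if (any(diff(lambdas) >= 0))
    stop("infeasible plan: spacings are not strictly decreasing; increase beta or N")

  J <- alpha * n / lambdas^2
  deltas <- sqrt(local_mse_power_law(J, g, eps))
  taus <- optimal_tau(J, motion)

  structure(list(
    params = list(N = as.integer(N), m = as.integer(m), lambda1 = lambda1,
                  beta = beta, alpha = alpha, rmax = rmax,
                  sigma_over_lambda = sigma_over_lambda, motion = motion),
    n = n, n_exact = n_exact, lambdas = lambdas, J = J, deltas = deltas,
    taus = taus), class = "module_plan")
}

#' Maximum feasible number of modules
#'
#' The largest \code{m} such that a geometric allocation of \code{N} neurons
#' with successive-module population ratio \code{pop_ratio} leaves at least
#' one neuron in the smallest-population (largest-spacing) module.
#'
#' @param N total number of neurons.
#' @param pop_ratio successive-module population ratio (> 1).
#' @return integer module count.
#' @export
max_modules <- function(N, pop_ratio) {
  stopifnot(N >= 1, pop_ratio > 1)
  m <- 1L
  repeat {
    w <- pop_ratio^(seq_len(m + 1L))
    n1 <- N * w[1] / sum(w)
    if (n1 < 1) return(m)
    m <- m + 1L
    if (m > 10000L) stop("pop_ratio too close to 1")
  }
}

#' @export
print.module_plan <- function(x, ...) {
  p <- x$params
  mot <- if (p$motion$kind == "random_walk")
    sprintf("random walk (D = %g m^2/s)", p$motion$D)
  else sprintf("power law (g = %g, epsilon = %g)", p$motion$g,
               p$motion$epsilon)
  cat(sprintf(
    "module_plan: N = %d neurons, m = %d modules, lambda1 = %g m, beta = %g\n",
    p$N, p$m, p$lambda1, p$beta))
  cat(sprintf("motion: %s; alpha = %.4g 1/s\n", mot, p$alpha))
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.module_plan <- function(x, ...) {
  data.frame(module = seq_along(x$n), n = x$n, lambda_m = x$lambdas,
             delta_m = x$deltas, tau_s = x$taus)
}

#' @export
summary.module_plan <- function(object, ...) {
  m <- length(object$n)
  cat(sprintf("spacing ratios lambda_i/lambda_{i+1}: %s (limit %.4g)\n",
              paste(sprintf("%.4g", object$lambdas[-m] / object$lambdas[-1]),
                    collapse = ", "),
              spacing_ratio_limit(object$params$motion$epsilon)))
  cat(sprintf("tau range: %.4g .. %.4g s\n", min(object$taus),
              max(object$taus)))
  cat(sprintf("finest predicted local RMSE: %.4g cm\n",
              100 * min(object$deltas)))
  invisible(object)
}

#' @export
plot.module_plan <- function(x, ...) {
  par(mfrow = c(1, 2))
  plot(seq_along(x$n), x$n, log = "y", xlab = "module", ylab = "neurons",
       type = "b", main = "population sizes", ...)
  plot(seq_along(x$lambdas), x$lambdas, log = "y", xlab = "module",
       ylab = "spacing (m)", type = "b", main = "grid spacings", ...)
  par(mfrow = c(1, 1))
  invisible(x)
}

#' Write / read a module plan as JSON
#'
#' @param plan a \code{module_plan}.
#' @param path file path.
#' @return \code{read_plan} returns a \code{module_plan}.
#' @export
write_plan <- function(plan, path) {
  doc <- unclass(plan)
  doc$params$motion <- unclass(doc$params$motion)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  mot <- doc$params$motion
  doc$params$motion <- if (mot$kind == "random_walk")
    motion_random_walk(mot$D) else motion_power_law(mot$g, mot$epsilon)
  doc$n <- as.integer(doc$n)
  doc$params$N <- as.integer(doc$params$N)
  doc$params$m <- as.integer(doc$params$m)
  structure(doc, class = "module_plan")
}

#' Re-allocate a plan's neurons across its modules
#'
#' Keeps the plan's spacings but redistributes the \code{N} neurons:
#' \code{"optimal"} returns the plan unchanged, \code{"equal"} splits neurons
#' evenly, \code{"reversed"} reverses the optimal counts (most neurons in the
#' coarsest module). Fisher rates, predicted resolutions and readout
#' constants are recomputed from the new counts.
#'
#' @param plan a \code{module_plan}.
#' @param scheme allocation scheme.
#' @return a \code{module_plan}.
#' @export
reallocate <- function(plan, scheme = c("optimal", "equal", "reversed")) {
  scheme <- match.arg(scheme)
  n <- switch(scheme,
              optimal = plan$n,
              equal = largest_remainder(rep(plan$params$N / length(plan$n),
                                            length(plan$n)), plan$params$N),
              reversed = rev(plan$n))
  out <- plan
  out$n <- n
  out$n_exact <- as.numeric(n)
  mot <- plan$params$motion
  out$J <- plan$params$alpha * n / plan$lambdas^2
  out$deltas <- sqrt(local_mse_power_law(out$J, mot$g, mot$epsilon))
  out$taus <- optimal_tau(out$J, mot)
  out$allocation <- scheme
  out
}
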