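# Inhomogeneous Poisson spike generation and binning.

# flatten population parameters for the C++ kernels
pop_arrays <- function(pop) {
  m <- length(pop$modules)
  list(
    lambda = vapply(pop$modules, `[[`, 1, "spacing"),
    theta = vapply(pop$modules, `[[`, 1, "orientation"),
    sigma = vapply(pop$modules, `[[`, 1, "sigma"),
    rmax = vapply(pop$modules, `[[`, 1, "rmax"),
    module = unlist(lapply(seq_len(m), function(i)
      rep(i - 1L, pop$modules[[i]]$n_cells))),
    phx = unlist(lapply(pop$modules, function(mo) mo$phases[, 1])),
    phy = unlist(lapply(pop$modules, function(mo) mo$phases[, 2])),
    cell = unlist(lapply(pop$modules, function(mo) seq_len(mo$n_cells))))
}

new_spike_raster <- function(times, duration, module, cell) {
  structure(list(times = times, n_neurons = length(times),
                 duration = duration, module = as.integer(module),
                 cell = as.integer(cell)),
            class = "spike_raster")
}

#' Generate inhomogeneous Poisson spikes
#'
#' Each cell fires as an independent Poisson process whose rate is its tuning
#' curve evaluated at the instantaneous (wrapped, if the trajectory has a
#' periodic domain) position. Implemented as per-bin Poisson draws at the
#' trajectory time step, with the rate treated as constant within each bin
#' (evaluated at the bin-start position); spike times are placed uniformly
#' within their bin. Deterministic given \code{seed}.
#'
#' @param pop a \code{grid_population}.
#' @param traj a \code{trajectory}.
#' @param seed integer seed.
#' @param tol lattice-sum truncation tolerance.
#' @return an object of class \code{spike_raster}: per-neuron sorted spike
#'   times, neuron-to-(module, cell) mapping and the duration.
#' @export
generate_spikes <- function(pop, traj, seed, tol = 1e-12) {
  if (traj$duration <= 0) stop("trajectory duration must be positive")
  pa <- pop_arrays(pop)
  nbins <- nrow(traj$positions) - 1L
  xs <- traj$positions[seq_len(nbins), 1]
  ys <- traj$positions[seq_len(nbins), 2]
  set.seed(as.integer(seed))
  ev <- cpp_generate_spikes(xs, ys, traj$dt, pa$lambda, pa$theta, pa$sigma,
                            pa$rmax, pa$module, pa$phx, pa$phy, tol)
  jitter <- runif(length(ev$bin))
  t_spk <- (ev$bin + jitter) * traj$dt
  times <- vector("list", pop$total_n)
  for (i in seq_len(pop$total_n)) times[[i]] <- numeric(0)
  if (length(ev$neuron) > 0) {
    # expand multi-spike bins into individual spike times
    reps <- ev$count
    neu <- rep(ev$neuron, reps)
    base_bin <- rep(ev$bin, reps)
    extra <- which(reps > 1)
    tt <- rep(t_spk, reps)
    if (length(extra) > 0) {
      more <- sum(reps[extra] - 1L)
      add_jit <- runif(more)
      pos <- which(duplicated(paste(neu, base_bin)))
      tt[pos] <- (base_bin[pos] + add_jit) * traj$dt
    }
    sp <- split(tt, neu)
    for (nm in names(sp)) times[[as.integer(nm)]] <- sort(sp[[nm]])
  }
  new_spike_raster(times, traj$duration, pa$module + 1L, pa$cell)
}

#' @export
print.spike_raster <- function(x, ...) {
  total <- sum(lengths(x$times))
  cat(sprintf(
    "spike_raster: %d neurons, %d spikes over %g s (mean rate %.3g Hz/neuron)\n",
    x$n_neurons, total, x$duration, total / x$n_neurons / x$duration))
  invisible(x)
}

#' Bin spikes into counts
#'
#' Counts spikes per half-open time bin \code{[k*dt, (k+1)*dt)}. Returned as
#' a sparse (bin, neuron, count) triplet object; use \code{as.matrix} for a
#' dense neurons-by-bins count matrix.
#'
#' @param raster a \code{spike_raster}.
#' @param dt bin width (s).
#' @param n_bins number of bins (defaults to \code{ceiling(duration/dt)}).
#' @return an object of class \code{spike_counts}.
#' @export
bin_spikes <- function(raster, dt, n_bins = NULL) {
  stop_if_not_scalar_pos(dt, "dt")
  n_bins <- as.integer(n_bins %||% max(1, round(raster$duration / dt)))
  all_t <- unlist(raster$times)
  neuron <- rep(seq_len(raster$n_neurons), lengths(raster$times))
  # guard against roundoff at exact bin boundaries (half-open convention)
  bin <- as.integer(floor(all_t / dt + 1e-9))
  bin[bin >= n_bins] <- n_bins - 1L
  key <- paste(bin, neuron)
  first <- !duplicated(key)
  count <- as.integer(table(factor(key, levels = key[first])))
  bin <- bin[first]
  neuron <- neuron[first]
  ord <- order(bin, neuron)
  structure(list(bin = bin[ord], neuron = neuron[ord], count = count[ord],
                 n_neurons = raster$n_neurons, n_bins = n_bins, dt = dt),
            class = "spike_counts")
}

#' @export
as.matrix.spike_counts <- function(x, ...) {
  M <- matrix(0L, x$n_neurons, x$n_bins)
  M[cbind(x$neuron, x$bin + 1L)] <- x$count
  M
}

#' @export
print.spike_counts <- function(x, ...) {
  cat(sprintf("spike_counts: %d neurons x %d bins of %g s, %d spikes\n",
              x$n_neurons, x$n_bins, x$dt, sum(x$count)))
  invisible(x)
}

#' Spike raster I/O
#'
#' Rasters are stored as delimited text with header \code{neuron_id,t} (one
#' spike per row) plus a JSON sidecar (same path with extension
#' \code{.json}) mapping each neuron to its (module, cell) and recording the
#' duration.
#'
#' @param raster a \code{spike_raster}.
#' @param path file path for the spike table.
#' @return \code{read_raster} returns a \code{spike_raster}.
#' @export
write_raster <- function(raster, path) {
  neuron <- rep(seq_len(raster$n_neurons), lengths(raster$times))
  df <- data.frame(neuron_id = neuron, t = unlist(raster$times))
  con <- file(path, "w")
  writeLines("neuron_id,t", con)
  if (nrow(df) > 0)
    write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                con, sep = ",", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
  close(con)
  jsonlite::write_json(
    list(n_neurons = raster$n_neurons, duration = raster$duration,
         module = raster$module, cell = raster$cell),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read.table(path, sep = ",", header = TRUE, comment.char = "#")
  times <- vector("list", meta$n_neurons)
  for (i in seq_len(meta$n_neurons)) times[[i]] <- numeric(0)
  if (nrow(df) > 0) {
    sp <- split(df$t, df$neuron_id)
    for (nm in names(sp)) times[[as.integer(nm)]] <- sort(sp[[nm]])
  }
  new_spike_raster(times, meta$duration, meta$module, meta$cell)
}
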