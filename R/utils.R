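# Internal helpers shared across modules.

# normalize a domain argument to c(Lx, Ly)
as_domain <- function(domain) {
  if (is.null(domain)) return(NULL)
  domain <- as.numeric(domain)
  if (length(domain) == 1) domain <- c(domain, domain)
  if (length(domain) != 2 || any(!is.finite(domain)) || any(domain <= 0))
    stop("`domain` must be a positive side length or a pair (Lx, Ly)")
  domain
}

# wrap an n x 2 matrix of positions onto the torus [0, Lx) x [0, Ly)
wrap_positions <- function(xy, domain) {
  domain <- as_domain(domain)
  cbind(xy[, 1] %% domain[1], xy[, 2] %% domain[2])
}

# squared toroidal distance between rows of two n x 2 matrices
toroidal_dist2 <- function(a, b, domain) {
  domain <- as_domain(domain)
  dx <- abs(a[, 1] - b[, 1]) %% domain[1]
  dx <- pmin(dx, domain[1] - dx)
  dy <- abs(a[, 2] - b[, 2]) %% domain[2]
  dy <- pmin(dy, domain[2] - dy)
  dx^2 + dy^2
}

# round positive fractional counts to integers with an exact total
# (largest-remainder method; ties resolved toward earlier entries)
largest_remainder <- function(frac, total) {
  stopifnot(all(frac >= 0), abs(sum(frac) - total) < 1e-6)
  base <- floor(frac)
  left <- as.integer(round(total - sum(base)))
  if (left > 0) {
    ord <- order(-(frac - base), seq_along(frac))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a positive finite scalar", name))
  invisible(x)
}

# derive a per-task RNG seed from a base seed, staying within 32-bit range
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 9973) %% 2147483587) + 1L
}

# 1D discrete Gaussian kernel with exact second moment; mirrors the C++
# construction so the reference R filter and the fused C++ filter agree
gauss_kernel_r <- function(sigma, res) {
  if (sigma <= 0) return(1)
  a <- sigma^2 / (2 * res^2)
  if (a <= 0.25) return(c(a, 1 - 2 * a, a))
  target <- sigma^2
  sig <- sigma
  for (it in 1:6) {
    R <- max(2, ceiling(5 * sig / res))
    k <- (-R):R
    w <- pnorm((k + 0.5) * res / sig) - pnorm((k - 0.5) * res / sig)
    w <- w / sum(w)
    v <- sum(w * (k * res)^2)
    if (abs(v - target) < 1e-10 * target) break
    sig <- sig * sqrt(target / v)
  }
  w
}

# wrapped 1D convolution of the columns/rows of a matrix with a centred kernel
conv_wrap_mat <- function(M, w, along = 1) {
  R <- (length(w) - 1) / 2
  n <- dim(M)[along]
  out <- 0 * M
  for (k in -R:R) {
    idx <- ((seq_len(n) - 1 - k) %% n) + 1
    out <- out + w[k + R + 1] * (if (along == 1) M[idx, , drop = FALSE]
                                 else M[, idx, drop = FALSE])
  }
  out
}
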