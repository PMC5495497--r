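// Core numerics: periodic Gaussian grid fields, inhomogeneous Poisson spike
// generation, the recursive Bayesian position filter and the kernel
// (filtered-spike-count) decoder on a periodic rectangular domain.
//
// Conventions shared with the R level:
//  - a module's firing-field lattice is triangular with basis
//    b1 = lambda*(1,0), b2 = lambda*(1/2, sqrt(3)/2), rotated by the module
//    orientation; "lattice coordinates" (u,v) are coefficients in this basis;
//  - posterior grids are nx*ny column-major vectors, node centres at
//    ((ix+0.5)*res, (iy+0.5)*res) on a torus of side (Lx, Ly);
//  - spikes arrive as (bin, neuron, count) triplets sorted by bin; the rate in
//    bin k is evaluated at the trajectory position at the start of the bin.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <deque>
#include <limits>

using namespace Rcpp;

static const double SQRT3_2 = 0.8660254037844386;
static const double INV_SQRT3_2 = 1.1547005383792515;
static const double NEG_INF = -std::numeric_limits<double>::infinity();

// lattice coordinates of the offset (x,y)-(px,py) in the frame of a module
// with orientation theta (cos/sin precomputed) and spacing lambda
static inline void latt_coords(double x, double y, double px, double py,
                               double c, double s, double lambda,
                               double &u, double &v) {
  double dx = x - px, dy = y - py;
  double rx = c * dx + s * dy;   // rotate by -theta
  double ry = -s * dx + c * dy;
  v = ry / (lambda * SQRT3_2);
  u = rx / lambda - 0.5 * v;
}

// firing rate at fractional lattice offset (du,dv): sum of Gaussians at the
// lattice points within radius rstar of the query point
static inline double rate_latt(double du, double dv, double lambda,
                               double sigma, double rmax, double rstar2,
                               int K) {
  du -= std::floor(du);
  dv -= std::floor(dv);
  double inv_s2 = 1.0 / (2.0 * sigma * sigma);
  double r = 0.0;
  for (int a = -K; a <= K + 1; ++a) {
    double uu = du - a;
    for (int b = -K; b <= K + 1; ++b) {
      double vv = dv - b;
      double rx = lambda * (uu + 0.5 * vv);
      double ry = lambda * (SQRT3_2 * vv);
      double d2 = rx * rx + ry * ry;
      if (d2 <= rstar2) r += std::exp(-d2 * inv_s2);
    }
  }
  return rmax * r;
}

static inline double rstar2_for(double sigma, double tol) {
  if (tol <= 0) tol = 1e-12;
  double rs = sigma * std::sqrt(2.0 * std::log(1.0 / tol));
  return rs * rs;
}

static inline int rings_for(double sigma, double lambda, double tol) {
  double rs = std::sqrt(rstar2_for(sigma, tol));
  int K = (int)std::ceil(rs / lambda * INV_SQRT3_2);
  return K < 1 ? 1 : K;
}

// [[Rcpp::export]]
NumericVector cpp_firing_rate(NumericVector x, NumericVector y, double lambda,
                              double theta, double sigma, double rmax,
                              double px, double py, double tol) {
  int n = x.size();
  NumericVector out(n);
  double c = std::cos(theta), s = std::sin(theta);
  double rs2 = rstar2_for(sigma, tol);
  int K = rings_for(sigma, lambda, tol);
  for (int i = 0; i < n; ++i) {
    double u, v;
    latt_coords(x[i], y[i], px, py, c, s, lambda, u, v);
    out[i] = rate_latt(u, v, lambda, sigma, rmax, rs2, K);
  }
  return out;
}

// rate template on the unit cell: value at (a/nt, b/nt) in lattice coords
// [[Rcpp::export]]
NumericMatrix cpp_cell_template(int nt, double lambda, double sigma,
                                double rmax, double tol) {
  NumericMatrix T(nt, nt);
  double rs2 = rstar2_for(sigma, tol);
  int K = rings_for(sigma, lambda, tol);
  for (int b = 0; b < nt; ++b) {
    double v = (double)b / nt;
    for (int a = 0; a < nt; ++a) {
      double u = (double)a / nt;
      T(a, b) = rate_latt(u, v, lambda, sigma, rmax, rs2, K);
    }
  }
  return T;
}

// sample a unit-cell map (nt x nt, lattice coords) at the nodes of the
// decoding grid, for a module with given spacing/orientation and zero phase
// [[Rcpp::export]]
NumericVector cpp_sample_cell_map(NumericMatrix cellmap, int nx, int ny,
                                  double res, double lambda, double theta) {
  int nt = cellmap.nrow();
  NumericVector out(nx * ny);
  double c = std::cos(theta), s = std::sin(theta);
  for (int iy = 0; iy < ny; ++iy) {
    double yy = (iy + 0.5) * res;
    for (int ix = 0; ix < nx; ++ix) {
      double xx = (ix + 0.5) * res;
      double u, v;
      latt_coords(xx, yy, 0.0, 0.0, c, s, lambda, u, v);
      u -= std::floor(u);
      v -= std::floor(v);
      double gu = u * nt, gv = v * nt;
      int i0 = (int)gu, j0 = (int)gv;
      double fu = gu - i0, fv = gv - j0;
      i0 %= nt; j0 %= nt;
      int i1 = (i0 + 1) % nt, j1 = (j0 + 1) % nt;
      out[ix + nx * iy] =
          (1 - fu) * (1 - fv) * cellmap(i0, j0) + fu * (1 - fv) * cellmap(i1, j0) +
          (1 - fu) * fv * cellmap(i0, j1) + fu * fv * cellmap(i1, j1);
    }
  }
  return out;
}

// inhomogeneous Poisson spikes: per-bin Poisson draws at the per-bin rate.
// positions are one per bin (start-of-bin); draw order is bin-major then
// neuron, so results are reproducible for a given R RNG state.
// [[Rcpp::export]]
List cpp_generate_spikes(NumericVector xs, NumericVector ys, double dt,
                         NumericVector mod_lambda, NumericVector mod_theta,
                         NumericVector mod_sigma, NumericVector mod_rmax,
                         IntegerVector neuron_module, NumericVector phx,
                         NumericVector phy, double tol) {
  int nbins = xs.size();
  int nneur = neuron_module.size();
  int m = mod_lambda.size();

  std::vector<double> cth(m), sth(m), rs2(m);
  std::vector<int> K(m);
  for (int i = 0; i < m; ++i) {
    cth[i] = std::cos(mod_theta[i]);
    sth[i] = std::sin(mod_theta[i]);
    rs2[i] = rstar2_for(mod_sigma[i], tol);
    K[i] = rings_for(mod_sigma[i], mod_lambda[i], tol);
  }
  // lattice coords of each neuron's phase
  std::vector<double> un(nneur), vn(nneur);
  for (int n = 0; n < nneur; ++n) {
    int md = neuron_module[n];
    latt_coords(phx[n], phy[n], 0.0, 0.0, cth[md], sth[md], mod_lambda[md],
                un[n], vn[n]);
  }

  std::vector<int> out_neu, out_bin, out_cnt;
  std::vector<double> ub(m), vb(m);
  for (int b = 0; b < nbins; ++b) {
    for (int i = 0; i < m; ++i)
      latt_coords(xs[b], ys[b], 0.0, 0.0, cth[i], sth[i], mod_lambda[i], ub[i],
                  vb[i]);
    for (int n = 0; n < nneur; ++n) {
      int md = neuron_module[n];
      double rate = rate_latt(ub[md] - un[n], vb[md] - vn[n], mod_lambda[md],
                              mod_sigma[md], mod_rmax[md], rs2[md], K[md]);
      double mu = rate * dt;
      int k = (mu > 0) ? (int)R::rpois(mu) : 0;
      if (k > 0) {
        out_neu.push_back(n + 1);
        out_bin.push_back(b);
        out_cnt.push_back(k);
      }
    }
  }
  return List::create(_["neuron"] = wrap(out_neu), _["bin"] = wrap(out_bin),
                      _["count"] = wrap(out_cnt));
}

// 1D wrapped Gaussian kernel with exact second moment. For very small
// sigma/res a three-tap kernel matches the variance exactly; otherwise an
// integrated (bin-averaged) Gaussian is rescaled by fixed-point iteration so
// its discrete variance equals sigma^2.
static std::vector<double> gauss_kernel(double sigma, double res) {
  std::vector<double> w;
  if (sigma <= 0) {
    w.push_back(1.0);
    return w;
  }
  double a = sigma * sigma / (2.0 * res * res);
  if (a <= 0.25) {
    w.resize(3);
    w[0] = a;
    w[1] = 1.0 - 2.0 * a;
    w[2] = a;
    return w;
  }
  double target = sigma * sigma, sig = sigma;
  const double inv_sqrt2 = 0.7071067811865475;
  int R = 2;
  for (int it = 0; it < 6; ++it) {
    R = std::max(2, (int)std::ceil(5.0 * sig / res));
    w.assign(2 * R + 1, 0.0);
    double sum = 0, var = 0;
    for (int k = -R; k <= R; ++k) {
      double hi = ((k + 0.5) * res) / sig, lo = ((k - 0.5) * res) / sig;
      double wk = 0.5 * (std::erf(hi * inv_sqrt2) - std::erf(lo * inv_sqrt2));
      w[k + R] = wk;
      sum += wk;
      var += wk * (double)k * k * res * res;
    }
    var /= sum;
    for (size_t j = 0; j < w.size(); ++j) w[j] /= sum;
    if (std::fabs(var - target) < 1e-10 * target) break;
    sig *= std::sqrt(target / var);
  }
  return w;
}

// fold a kernel longer than the ring onto it
static std::vector<double> fold_kernel(const std::vector<double> &w, int n) {
  int R = ((int)w.size() - 1) / 2;
  if (2 * R + 1 <= n) return w;
  std::vector<double> f(n, 0.0);
  for (int k = -R; k <= R; ++k) {
    int idx = ((k % n) + n) % n;
    f[idx] += w[k + R];
  }
  return f;  // interpreted as offsets 0..n-1
}

static void conv_wrap_x(const double *in, double *out, int nx, int ny,
                        const std::vector<double> &w, int R) {
  for (int j = 0; j < ny; ++j) {
    const double *row = in + (size_t)nx * j;
    double *orow = out + (size_t)nx * j;
    for (int i = 0; i < nx; ++i) {
      double s = 0;
      for (int k = -R; k <= R; ++k) {
        int idx = i - k;
        if (idx < 0) idx += nx;
        else if (idx >= nx) idx -= nx;
        s += w[k + R] * row[idx];
      }
      orow[i] = s;
    }
  }
}

static void conv_wrap_y(const double *in, double *out, int nx, int ny,
                        const std::vector<double> &w, int R) {
  for (int j = 0; j < ny; ++j) {
    double *orow = out + (size_t)nx * j;
    for (int i = 0; i < nx; ++i) orow[i] = 0.0;
    for (int k = -R; k <= R; ++k) {
      int jj = j - k;
      if (jj < 0) jj += ny;
      else if (jj >= ny) jj -= ny;
      const double *row = in + (size_t)nx * jj;
      double wk = w[k + R];
      for (int i = 0; i < nx; ++i) orow[i] += wk * row[i];
    }
  }
}

// generic wrapped convolution when the kernel was folded (offsets 0..n-1)
static void conv_fold_x(const double *in, double *out, int nx, int ny,
                        const std::vector<double> &f) {
  for (int j = 0; j < ny; ++j) {
    const double *row = in + (size_t)nx * j;
    double *orow = out + (size_t)nx * j;
    for (int i = 0; i < nx; ++i) {
      double s = 0;
      for (int k = 0; k < nx; ++k) {
        int idx = i - k;
        if (idx < 0) idx += nx;
        s += f[k] * row[idx];
      }
      orow[i] = s;
    }
  }
}

static void conv_fold_y(const double *in, double *out, int nx, int ny,
                        const std::vector<double> &f) {
  for (int j = 0; j < ny; ++j) {
    double *orow = out + (size_t)nx * j;
    for (int i = 0; i < nx; ++i) orow[i] = 0.0;
    for (int k = 0; k < ny; ++k) {
      int jj = j - k;
      if (jj < 0) jj += ny;
      const double *row = in + (size_t)nx * jj;
      double wk = f[k];
      for (int i = 0; i < nx; ++i) orow[i] += wk * row[i];
    }
  }
}

static inline double tor_d2(double ax, double ay, double bx, double by,
                            double Lx, double Ly) {
  double dx = std::fabs(ax - bx);
  if (dx > 0.5 * Lx) dx = Lx - dx;
  double dy = std::fabs(ay - by);
  if (dy > 0.5 * Ly) dy = Ly - dy;
  return dx * dx + dy * dy;
}

// quadratic (3-point) refinement of a discrete peak along one axis
static inline double refine1(double l, double c, double r) {
  if (!std::isfinite(l) || !std::isfinite(r) || !std::isfinite(c)) return 0.0;
  double denom = l - 2.0 * c + r;
  if (denom >= 0) return 0.0;
  double d = (l - r) / (2.0 * denom);
  if (d > 0.5) d = 0.5;
  if (d < -0.5) d = -0.5;
  return d;
}

struct EstOut {
  double x, y;
};

static EstOut argmax_estimate(const std::vector<double> &logp, int nx, int ny,
                              double res, bool refine) {
  int imax = 0;
  double best = logp[0];
  int nn = nx * ny;
  for (int i = 1; i < nn; ++i)
    if (logp[i] > best) {
      best = logp[i];
      imax = i;
    }
  int ix = imax % nx, iy = imax / nx;
  double dx = 0, dy = 0;
  if (refine) {
    double l = logp[(ix == 0 ? nx - 1 : ix - 1) + nx * iy];
    double r = logp[(ix == nx - 1 ? 0 : ix + 1) + nx * iy];
    dx = refine1(l, best, r);
    double d = logp[ix + nx * (iy == 0 ? ny - 1 : iy - 1)];
    double u = logp[ix + nx * (iy == ny - 1 ? 0 : iy + 1)];
    dy = refine1(d, best, u);
  }
  EstOut e;
  e.x = (ix + 0.5 + dx) * res;
  e.y = (iy + 0.5 + dy) * res;
  return e;
}

// nearest-peak squared toroidal distance; peaks are strict local maxima over
// the 8-neighbourhood with log density >= max + log_rel_tol
static double nearest_peak_err2(const std::vector<double> &logp, int nx,
                                int ny, double res, double Lx, double Ly,
                                double log_rel_tol, bool refine, double tx,
                                double ty, int *npeaks) {
  int nn = nx * ny;
  double mx = NEG_INF;
  for (int i = 0; i < nn; ++i)
    if (logp[i] > mx) mx = logp[i];
  double thr = mx + log_rel_tol;
  double best = std::numeric_limits<double>::infinity();
  int count = 0;
  for (int iy = 0; iy < ny; ++iy) {
    int ym = (iy == 0 ? ny - 1 : iy - 1), yp = (iy == ny - 1 ? 0 : iy + 1);
    for (int ix = 0; ix < nx; ++ix) {
      double c = logp[ix + nx * iy];
      if (c < thr || !std::isfinite(c)) continue;
      int xm = (ix == 0 ? nx - 1 : ix - 1), xp = (ix == nx - 1 ? 0 : ix + 1);
      if (c <= logp[xm + nx * iy] || c <= logp[xp + nx * iy]) continue;
      if (c <= logp[ix + nx * ym] || c <= logp[ix + nx * yp]) continue;
      if (c <= logp[xm + nx * ym] || c <= logp[xp + nx * ym]) continue;
      if (c <= logp[xm + nx * yp] || c <= logp[xp + nx * yp]) continue;
      ++count;
      double dx = 0, dy = 0;
      if (refine) {
        dx = refine1(logp[xm + nx * iy], c, logp[xp + nx * iy]);
        dy = refine1(logp[ix + nx * ym], c, logp[ix + nx * yp]);
      }
      double px = (ix + 0.5 + dx) * res, py = (iy + 0.5 + dy) * res;
      double d2 = tor_d2(px, py, tx, ty, Lx, Ly);
      if (d2 < best) best = d2;
    }
  }
  *npeaks = count;
  if (count == 0) return NA_REAL;
  return best;
}

// precompute, for every grid node and module, the node's lattice coordinates
static void node_latt(int nx, int ny, double res, double lambda, double theta,
                      std::vector<double> &U, std::vector<double> &V) {
  double c = std::cos(theta), s = std::sin(theta);
  for (int iy = 0; iy < ny; ++iy) {
    double yy = (iy + 0.5) * res;
    for (int ix = 0; ix < nx; ++ix) {
      double xx = (ix + 0.5) * res;
      double u, v;
      latt_coords(xx, yy, 0.0, 0.0, c, s, lambda, u, v);
      U[ix + nx * iy] = u;
      V[ix + nx * iy] = v;
    }
  }
}

static inline double bilinear_cell(const double *T, int nt, double u,
                                   double v) {
  u -= std::floor(u);
  v -= std::floor(v);
  double gu = u * nt, gv = v * nt;
  int i0 = (int)gu, j0 = (int)gv;
  double fu = gu - i0, fv = gv - j0;
  if (i0 >= nt) { i0 = 0; fu = 0; }
  if (j0 >= nt) { j0 = 0; fv = 0; }
  int i1 = (i0 + 1 == nt) ? 0 : i0 + 1;
  int j1 = (j0 + 1 == nt) ? 0 : j0 + 1;
  return (1 - fu) * (1 - fv) * T[i0 + nt * j0] + fu * (1 - fv) * T[i1 + nt * j0] +
         (1 - fu) * fv * T[i0 + nt * j1] + fu * fv * T[i1 + nt * j1];
}

// add k * log f_mu to the log posterior for one spiking neuron
static void add_spike_map(std::vector<double> &logp, const double *T, int nt,
                          const std::vector<double> &U,
                          const std::vector<double> &V, double un, double vn,
                          double k) {
  int nn = (int)logp.size();
  for (int i = 0; i < nn; ++i)
    logp[i] += k * bilinear_cell(T, nt, U[i] - un, V[i] - vn);
}

static inline double slog(double x) { return x > 0 ? std::log(x) : NEG_INF; }

// multiply a linear-space field by T^k sampled at each node's lattice offset
// from (un, vn); lattice coordinates are affine in (x, y), so they are
// advanced incrementally along each row
static void mul_field(std::vector<double> &p, int nx, int ny, double res,
                      double a11, double a12, double a21, double a22,
                      double un, double vn, const double *T, int nt, int k) {
  double dux = a11 * res, dvx = a21 * res;
  for (int iy = 0; iy < ny; ++iy) {
    double x0 = 0.5 * res, y0 = (iy + 0.5) * res;
    double u = a11 * x0 + a12 * y0 - un;
    double v = a21 * x0 + a22 * y0 - vn;
    double *row = p.data() + (size_t)nx * iy;
    if (k == 1) {
      for (int ix = 0; ix < nx; ++ix, u += dux, v += dvx)
        row[ix] *= bilinear_cell(T, nt, u, v);
    } else {
      for (int ix = 0; ix < nx; ++ix, u += dux, v += dvx)
        row[ix] *= std::pow(bilinear_cell(T, nt, u, v), (double)k);
    }
  }
}

// combine several same-module spikes into one multiplicative factor on the
// module's unit cell (node (a, b) sits at lattice coords (a/nt, b/nt))
static void build_factor(std::vector<double> &G, int nt, const double *T,
                         const std::vector<int> &idx,
                         const IntegerVector &sp_neuron,
                         const IntegerVector &sp_count,
                         const std::vector<double> &un,
                         const std::vector<double> &vn) {
  double step = 1.0 / nt;
  for (size_t s = 0; s < idx.size(); ++s) {
    int n = sp_neuron[idx[s]] - 1;
    int k = sp_count[idx[s]];
    double u0 = -un[n], v0 = -vn[n];
    int j = 0;
    for (int bg = 0; bg < nt; ++bg) {
      double v = v0 + bg * step;
      double u = u0;
      for (int ag = 0; ag < nt; ++ag, u += step, ++j) {
        double f = bilinear_cell(T, nt, u, v);
        if (k != 1) f = std::pow(f, (double)k);
        G[j] = (s == 0) ? f : G[j] * f;
      }
    }
  }
}

// linear-space counterparts of the peak utilities; quadratic refinement is
// performed on log values so results match the log-domain reference
static EstOut argmax_lin(const std::vector<double> &p, int imax, int nx,
                         int ny, double res, bool refine) {
  int ix = imax % nx, iy = imax / nx;
  double dx = 0, dy = 0;
  if (refine) {
    double c = slog(p[imax]);
    double l = slog(p[(ix == 0 ? nx - 1 : ix - 1) + nx * iy]);
    double r = slog(p[(ix == nx - 1 ? 0 : ix + 1) + nx * iy]);
    dx = refine1(l, c, r);
    double d = slog(p[ix + nx * (iy == 0 ? ny - 1 : iy - 1)]);
    double u = slog(p[ix + nx * (iy == ny - 1 ? 0 : iy + 1)]);
    dy = refine1(d, c, u);
  }
  EstOut e;
  e.x = (ix + 0.5 + dx) * res;
  e.y = (iy + 0.5 + dy) * res;
  return e;
}

static double nearest_peak_lin(const std::vector<double> &p, double mx,
                               int nx, int ny, double res, double Lx,
                               double Ly, double rel_tol, bool refine,
                               double tx, double ty, int *npeaks) {
  double thr = mx * rel_tol;
  double best = std::numeric_limits<double>::infinity();
  int count = 0;
  for (int iy = 0; iy < ny; ++iy) {
    int ym = (iy == 0 ? ny - 1 : iy - 1), yp = (iy == ny - 1 ? 0 : iy + 1);
    for (int ix = 0; ix < nx; ++ix) {
      double c = p[ix + nx * iy];
      if (!(c >= thr)) continue;
      int xm = (ix == 0 ? nx - 1 : ix - 1), xp = (ix == nx - 1 ? 0 : ix + 1);
      if (c <= p[xm + nx * iy] || c <= p[xp + nx * iy]) continue;
      if (c <= p[ix + nx * ym] || c <= p[ix + nx * yp]) continue;
      if (c <= p[xm + nx * ym] || c <= p[xp + nx * ym]) continue;
      if (c <= p[xm + nx * yp] || c <= p[xp + nx * yp]) continue;
      ++count;
      double dx = 0, dy = 0;
      if (refine) {
        double lc = slog(c);
        dx = refine1(slog(p[xm + nx * iy]), lc, slog(p[xp + nx * iy]));
        dy = refine1(slog(p[ix + nx * ym]), lc, slog(p[ix + nx * yp]));
      }
      double px = (ix + 0.5 + dx) * res, py = (iy + 0.5 + dy) * res;
      double d2 = tor_d2(px, py, tx, ty, Lx, Ly);
      if (d2 < best) best = d2;
    }
  }
  *npeaks = count;
  if (count == 0) return NA_REAL;
  return best;
}

// [[Rcpp::export]]
List cpp_bayes_decode(int nx, int ny, double res, NumericVector log_prior,
                      IntegerVector sp_bin, IntegerVector sp_neuron,
                      IntegerVector sp_count, int nbins, double dt, double D,
                      NumericMatrix log_templates, int nt,
                      NumericVector mod_lambda, NumericVector mod_theta,
                      IntegerVector neuron_module, NumericVector phx,
                      NumericVector phy, NumericVector total_rate,
                      int est_every, NumericVector truth_x,
                      NumericVector truth_y, double log_rel_tol, bool refine,
                      bool keep_log) {
  int nn = nx * ny;
  int m = mod_lambda.size();
  int nneur = neuron_module.size();
  int ntt = nt * nt;
  double Lx = nx * res, Ly = ny * res;
  bool want_local = truth_x.size() == nbins;
  double rel_tol = std::exp(log_rel_tol);

  // the posterior is kept in linear space (diffusion, zero-count decay and
  // spike factors are all multiplicative there) and renormalized by its
  // maximum once per bin to keep the dynamic range bounded
  std::vector<double> p(nn), buf(nn);
  {
    double mx = NEG_INF;
    for (int i = 0; i < nn; ++i)
      if (log_prior[i] > mx) mx = log_prior[i];
    for (int i = 0; i < nn; ++i) p[i] = std::exp(log_prior[i] - mx);
  }

  // per-bin zero-count likelihood exp(-dt * total rate), computed once
  std::vector<double> decay(nn);
  for (int i = 0; i < nn; ++i) decay[i] = std::exp(-dt * total_rate[i]);

  // linear rate templates on each module's unit cell
  std::vector<std::vector<double>> F(m, std::vector<double>(ntt));
  for (int md = 0; md < m; ++md)
    for (int j = 0; j < ntt; ++j) F[md][j] = std::exp(log_templates(j, md));

  // lattice coordinates are affine in (x, y): (u, v) = A (x, y)
  std::vector<double> a11(m), a12(m), a21(m), a22(m);
  for (int i = 0; i < m; ++i) {
    double c = std::cos(mod_theta[i]), s = std::sin(mod_theta[i]);
    a21[i] = -s / (mod_lambda[i] * SQRT3_2);
    a22[i] = c / (mod_lambda[i] * SQRT3_2);
    a11[i] = c / mod_lambda[i] - 0.5 * a21[i];
    a12[i] = s / mod_lambda[i] - 0.5 * a22[i];
  }
  std::vector<double> un(nneur), vn(nneur);
  for (int n = 0; n < nneur; ++n) {
    int md = neuron_module[n];
    double c = std::cos(mod_theta[md]), s = std::sin(mod_theta[md]);
    latt_coords(phx[n], phy[n], 0.0, 0.0, c, s, mod_lambda[md], un[n], vn[n]);
  }

  double sig_d = std::sqrt(2.0 * D * dt);
  std::vector<double> w = gauss_kernel(sig_d, res);
  int R = ((int)w.size() - 1) / 2;
  bool fold_x = (2 * R + 1) > nx, fold_y = (2 * R + 1) > ny;
  std::vector<double> wfx = fold_x ? fold_kernel(w, nx) : w;
  std::vector<double> wfy = fold_y ? fold_kernel(w, ny) : w;

  int nrec = 0;
  for (int b = 0; b < nbins; ++b)
    if ((b + 1) % est_every == 0) ++nrec;
  IntegerVector rec_bin(nrec);
  NumericVector est_x(nrec), est_y(nrec);
  NumericVector err2(want_local ? nrec : 0);
  IntegerVector npk(want_local ? nrec : 0);

  std::vector<std::vector<int>> batch(m);
  std::vector<double> G(ntt);

  double scale = 1.0;
  int si = 0, nsp = sp_bin.size(), ir = 0;
  for (int b = 0; b < nbins; ++b) {
    if (b > 0 && D > 0) {
      if (fold_x) conv_fold_x(p.data(), buf.data(), nx, ny, wfx);
      else conv_wrap_x(p.data(), buf.data(), nx, ny, wfx, R);
      if (fold_y) conv_fold_y(buf.data(), p.data(), nx, ny, wfy);
      else conv_wrap_y(buf.data(), p.data(), nx, ny, wfy, R);
    }
    // zero-count likelihood, fused with the pending renormalization; mass
    // this far below the peak is flushed to exact zero so the field never
    // drifts into the (slow) denormal range
    for (int i = 0; i < nn; ++i) {
      double v = p[i] * (scale * decay[i]);
      p[i] = (v < 1e-180) ? 0.0 : v;
    }

    // group this bin's spikes by module; a module's spikes combine into one
    // factor on its unit cell so the full grid is touched once per module
    for (int i = 0; i < m; ++i) batch[i].clear();
    while (si < nsp && sp_bin[si] == b) {
      batch[neuron_module[sp_neuron[si] - 1]].push_back(si);
      ++si;
    }
    for (int md = 0; md < m; ++md) {
      size_t ns = batch[md].size();
      if (ns == 0) continue;
      const double *T = F[md].data();
      if (ns == 1) {
        int s0 = batch[md][0];
        int n = sp_neuron[s0] - 1;
        mul_field(p, nx, ny, res, a11[md], a12[md], a21[md], a22[md], un[n],
                  vn[n], T, nt, sp_count[s0]);
      } else {
        build_factor(G, nt, T, batch[md], sp_neuron, sp_count, un, vn);
        mul_field(p, nx, ny, res, a11[md], a12[md], a21[md], a22[md], 0.0,
                  0.0, G.data(), nt, 1);
      }
    }

    // renormalize; the same scan yields the maximum-likelihood node
    double mx = 0.0;
    int imax = 0;
    for (int i = 0; i < nn; ++i)
      if (p[i] > mx) {
        mx = p[i];
        imax = i;
      }
    if (!(mx > 0.0) || !std::isfinite(mx))
      stop("posterior underflow: all probability mass lost; use a coarser "
           "time step or finer grid resolution");
    scale = 1.0 / mx;

    if ((b + 1) % est_every == 0) {
      EstOut e = argmax_lin(p, imax, nx, ny, res, refine);
      rec_bin[ir] = b;
      est_x[ir] = e.x;
      est_y[ir] = e.y;
      if (want_local) {
        int np = 0;
        err2[ir] = nearest_peak_lin(p, mx, nx, ny, res, Lx, Ly, rel_tol,
                                    refine, truth_x[b], truth_y[b], &np);
        npk[ir] = np;
      }
      ++ir;
    }
    if (b % 256 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(_["bin"] = rec_bin, _["est_x"] = est_x,
                          _["est_y"] = est_y);
  if (want_local) {
    out["local_err2"] = err2;
    out["n_peaks"] = npk;
  }
  if (keep_log) {
    double sum = 0;
    for (int i = 0; i < nn; ++i) sum += p[i];
    double ls = std::log(sum);
    NumericVector lp(nn);
    for (int i = 0; i < nn; ++i) lp[i] = slog(p[i]) - ls;
    out["log_posterior"] = lp;
  }
  return out;
}

// kernel decoder: per-module maps M_i(x) = sum over spikes of
// k * h_i(t - t') * log f_mu(x); exponential kernels decay lazily (a scalar
// per module applied when the module is touched), rectangular kernels expire
// spikes from a FIFO queue.
// [[Rcpp::export]]
List cpp_kernel_decode(int nx, int ny, double res, IntegerVector sp_bin,
                       IntegerVector sp_neuron, IntegerVector sp_count,
                       int nbins, double dt, NumericMatrix log_templates,
                       int nt, NumericVector mod_lambda,
                       NumericVector mod_theta, IntegerVector neuron_module,
                       NumericVector phx, NumericVector phy,
                       NumericVector tau, int shape, int est_every,
                       NumericVector truth_x, NumericVector truth_y,
                       double log_rel_tol, bool refine) {
  int nn = nx * ny;
  int m = mod_lambda.size();
  int nneur = neuron_module.size();
  double Lx = nx * res, Ly = ny * res;
  bool want_local = truth_x.size() == nbins;

  std::vector<std::vector<double>> U(m), V(m);
  for (int i = 0; i < m; ++i) {
    U[i].resize(nn);
    V[i].resize(nn);
    node_latt(nx, ny, res, mod_lambda[i], mod_theta[i], U[i], V[i]);
  }
  std::vector<double> un(nneur), vn(nneur);
  for (int n = 0; n < nneur; ++n) {
    int md = neuron_module[n];
    double c = std::cos(mod_theta[md]), s = std::sin(mod_theta[md]);
    latt_coords(phx[n], phy[n], 0.0, 0.0, c, s, mod_lambda[md], un[n], vn[n]);
  }

  std::vector<std::vector<double>> M(m, std::vector<double>(nn, 0.0));
  std::vector<int> last(m, 0);
  std::vector<int> wbin(m, 1);
  if (shape == 1)
    for (int i = 0; i < m; ++i) {
      wbin[i] = (int)std::lround(tau[i] / dt);
      if (wbin[i] < 1) wbin[i] = 1;
    }
  struct QE {
    int expire, neuron, count;
  };
  std::vector<std::deque<QE>> queue(shape == 1 ? m : 0);

  std::vector<double> total(nn);

  int nrec = 0;
  for (int b = 0; b < nbins; ++b)
    if ((b + 1) % est_every == 0) ++nrec;
  IntegerVector rec_bin(nrec);
  NumericVector est_x(nrec), est_y(nrec);
  NumericVector err2(want_local ? nrec : 0);
  IntegerVector npk(want_local ? nrec : 0);

  int si = 0, nsp = sp_bin.size(), ir = 0;
  for (int b = 0; b < nbins; ++b) {
    if (shape == 1) {
      for (int i = 0; i < m; ++i) {
        while (!queue[i].empty() && queue[i].front().expire <= b) {
          QE q = queue[i].front();
          queue[i].pop_front();
          add_spike_map(M[i], &log_templates(0, i), nt, U[i], V[i],
                        un[q.neuron], vn[q.neuron], -(double)q.count);
        }
      }
    }
    while (si < nsp && sp_bin[si] == b) {
      int n = sp_neuron[si] - 1;
      int md = neuron_module[n];
      if (shape == 0 && b > last[md]) {
        double f = std::exp(-(b - last[md]) * dt / tau[md]);
        for (int i = 0; i < nn; ++i) M[md][i] *= f;
        last[md] = b;
      }
      add_spike_map(M[md], &log_templates(0, md), nt, U[md], V[md], un[n],
                    vn[n], (double)sp_count[si]);
      if (shape == 1) {
        QE q;
        q.expire = b + wbin[md];
        q.neuron = n;
        q.count = sp_count[si];
        queue[md].push_back(q);
      }
      ++si;
    }
    if ((b + 1) % est_every == 0) {
      for (int i = 0; i < nn; ++i) total[i] = 0.0;
      for (int md = 0; md < m; ++md) {
        double wgt =
            (shape == 0) ? std::exp(-(b - last[md]) * dt / tau[md]) : 1.0;
        const double *src = M[md].data();
        for (int i = 0; i < nn; ++i) total[i] += wgt * src[i];
      }
      EstOut e = argmax_estimate(total, nx, ny, res, refine);
      rec_bin[ir] = b;
      est_x[ir] = e.x;
      est_y[ir] = e.y;
      if (want_local) {
        int np = 0;
        err2[ir] = nearest_peak_err2(total, nx, ny, res, Lx, Ly, log_rel_tol,
                                     refine, truth_x[b], truth_y[b], &np);
        npk[ir] = np;
      }
      ++ir;
    }
    if (b % 256 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(_["bin"] = rec_bin, _["est_x"] = est_x,
                          _["est_y"] = est_y);
  if (want_local) {
    out["local_err2"] = err2;
    out["n_peaks"] = npk;
  }
  return out;
}
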