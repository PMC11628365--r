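// Desk-scale biased-sampling engine: BAOAB Langevin dynamics on built-in toy
// landscapes, optionally biased by 1D well-tempered metadynamics on a
// collective variable (a coordinate, or a tabulated pathCV progress s with a
// tabulated orthogonal distance z under a one-sided harmonic wall).
// Uses R's RNG (norm_rand) so set.seed() governs reproducibility.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// potential ids: 0 harmonic, 1 double-well 1D, 2 two-channel 2D, 3 Mueller-Brown
static void potential_grad(int id, const NumericVector &par,
                           const double *x, int dim,
                           double *grad, double *energy) {
  double E = 0.0;
  for (int k = 0; k < dim; ++k) grad[k] = 0.0;
  if (id == 0) {                       // harmonic: par = (k, center)
    double kk = par[0], c = par[1];
    for (int k = 0; k < dim; ++k) {
      double d = x[k] - c;
      E += 0.5 * kk * d * d;
      grad[k] = kk * d;
    }
  } else if (id == 1) {                // A (x^2-1)^2 + eps x
    double A = par[0], eps = par[1], xx = x[0];
    E = A * (xx * xx - 1) * (xx * xx - 1) + eps * xx;
    grad[0] = 4 * A * xx * (xx * xx - 1) + eps;
  } else if (id == 2) {                // two-channel: A, C, delta, w, eps
    double A = par[0], C = par[1], del = par[2], w = par[3], eps = par[4];
    double xx = x[0], yy = x[1];
    double g = std::exp(-xx * xx / (w * w));
    E = A * (xx * xx - 1) * (xx * xx - 1) + C * (yy * yy - 1) * (yy * yy - 1) +
        del * yy * g + eps * xx;
    grad[0] = 4 * A * xx * (xx * xx - 1) - 2 * xx / (w * w) * del * yy * g + eps;
    grad[1] = 4 * C * yy * (yy * yy - 1) + del * g;
  } else if (id == 3) {                // Mueller-Brown
    static const double Ak[4] = {-200, -100, -170, 15};
    static const double ak[4] = {-1, -1, -6.5, 0.7};
    static const double bk[4] = {0, 0, 11, 0.6};
    static const double ck[4] = {-10, -10, -6.5, 0.7};
    static const double x0k[4] = {1, 0, -0.5, -1};
    static const double y0k[4] = {0, 0.5, 1.5, 1};
    double xx = x[0], yy = x[1];
    for (int k = 0; k < 4; ++k) {
      double dx = xx - x0k[k], dy = yy - y0k[k];
      double e = Ak[k] * std::exp(ak[k] * dx * dx + bk[k] * dx * dy + ck[k] * dy * dy);
      E += e;
      grad[0] += e * (2 * ak[k] * dx + bk[k] * dy);
      grad[1] += e * (bk[k] * dx + 2 * ck[k] * dy);
    }
  }
  *energy = E;
}

// bilinear interpolation of a table over a regular (x, y) grid, with clamped
// gradient by central differences
struct Table2D {
  const double *v;
  double x0, dx, y0, dy;
  int nx, ny;
  double at(int i, int j) const { return v[i + nx * j]; }
  double value(double x, double y, double *gx, double *gy) const {
    double fx = (x - x0) / dx, fy = (y - y0) / dy;
    int i = (int)std::floor(fx), j = (int)std::floor(fy);
    if (i < 0) i = 0; if (i > nx - 2) i = nx - 2;
    if (j < 0) j = 0; if (j > ny - 2) j = ny - 2;
    double tx = fx - i, ty = fy - j;
    if (tx < 0) tx = 0; if (tx > 1) tx = 1;
    if (ty < 0) ty = 0; if (ty > 1) ty = 1;
    double v00 = at(i, j), v10 = at(i + 1, j), v01 = at(i, j + 1), v11 = at(i + 1, j + 1);
    double val = v00 * (1 - tx) * (1 - ty) + v10 * tx * (1 - ty) +
                 v01 * (1 - tx) * ty + v11 * tx * ty;
    if (gx) *gx = ((v10 - v00) * (1 - ty) + (v11 - v01) * ty) / dx;
    if (gy) *gy = ((v01 - v00) * (1 - tx) + (v11 - v10) * tx) / dy;
    return val;
  }
};

// 1D bias grid helpers
static double bias_value(const std::vector<double> &b, double s0, double ds,
                         int ns, double s, double *gs) {
  double fs = (s - s0) / ds;
  int i = (int)std::floor(fs);
  if (i < 0) i = 0; if (i > ns - 2) i = ns - 2;
  double t = fs - i;
  if (t < 0) t = 0; if (t > 1) t = 1;
  if (gs) *gs = (b[i + 1] - b[i]) / ds;
  return b[i] * (1 - t) + b[i + 1] * t;
}

// [[Rcpp::export(name = ".run_engine")]]
List run_engine(int potential_id, NumericVector potential_params,
                NumericVector x0, int n_steps, double dt, double friction,
                double kT,
                int cv_mode,                // 0: s = x[0], no z; 1: tables
                NumericVector s_table, NumericVector z_table,
                NumericVector table_grid,   // x0, dx, nx, y0, dy, ny
                bool use_metad, double h0, double sigma_s, double bias_factor,
                int stride, double smin, double ds, int ns,
                bool use_wall, double wall_z0, double k_wall,
                int record_stride) {
  int dim = x0.size();
  std::vector<double> x(x0.begin(), x0.end()), v(dim, 0.0), grad(dim, 0.0);
  double energy = 0.0;
  Table2D ts, tz;
  if (cv_mode == 1) {
    ts.v = s_table.begin(); tz.v = z_table.begin();
    ts.x0 = tz.x0 = table_grid[0]; ts.dx = tz.dx = table_grid[1];
    ts.nx = tz.nx = (int)table_grid[2];
    ts.y0 = tz.y0 = table_grid[3]; ts.dy = tz.dy = table_grid[4];
    ts.ny = tz.ny = (int)table_grid[5];
  }
  std::vector<double> bias(ns > 0 ? ns : 1, 0.0);
  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt(kT * (1.0 - c1 * c1));

  int n_rec = n_steps / record_stride + 1;
  NumericMatrix traj(n_rec, dim + 3);   // t, x..., s, z? store: time, coords, s, z, bias
  // columns: 0 time, 1..dim coords, dim+1 s, dim+2 bias-at-frame (wall excluded)
  std::vector<double> hill_t, hill_c, hill_h;
  std::vector<double> ztraj(n_rec, 0.0);
  int irec = 0;

  auto cv_eval = [&](const std::vector<double> &q, double *dsdx, double *zval,
                     double *dzdx) {
    if (cv_mode == 0) {
      if (dsdx) { for (int k = 0; k < dim; ++k) dsdx[k] = 0.0; dsdx[0] = 1.0; }
      if (zval) *zval = 0.0;
      if (dzdx) for (int k = 0; k < dim; ++k) dzdx[k] = 0.0;
      return q[0];
    }
    double gx, gy, zgx, zgy;
    double s = ts.value(q[0], q[1], &gx, &gy);
    double z = tz.value(q[0], q[1], &zgx, &zgy);
    if (dsdx) { dsdx[0] = gx; dsdx[1] = gy; }
    if (zval) *zval = z;
    if (dzdx) { dzdx[0] = zgx; dzdx[1] = zgy; }
    return s;
  };

  std::vector<double> dsdx(dim, 0.0), dzdx(dim, 0.0), ftot(dim, 0.0);
  double zval = 0.0;

  auto total_force = [&](const std::vector<double> &q, double *fout,
                         double *bias_here, double *z_here) {
    potential_grad(potential_id, potential_params, q.data(), dim, grad.data(),
                   &energy);
    double s = cv_eval(q, dsdx.data(), &zval, dzdx.data());
    double vb = 0.0, gs = 0.0;
    if (use_metad && ns > 1) vb = bias_value(bias, smin, ds, ns, s, &gs);
    double fw = 0.0;
    if (use_wall && zval > wall_z0) fw = k_wall * (zval - wall_z0);
    for (int k = 0; k < dim; ++k)
      fout[k] = -grad[k] - gs * dsdx[k] - fw * dzdx[k];
    if (bias_here) *bias_here = vb;
    if (z_here) *z_here = zval;
    return s;
  };

  double bh, zh;
  double s_now = total_force(x, ftot.data(), &bh, &zh);
  traj(irec, 0) = 0;
  for (int k = 0; k < dim; ++k) traj(irec, 1 + k) = x[k];
  traj(irec, dim + 1) = s_now;
  traj(irec, dim + 2) = bh;
  ztraj[irec] = zh;
  ++irec;

  for (int step = 1; step <= n_steps; ++step) {
    // BAOAB
    for (int k = 0; k < dim; ++k) v[k] += 0.5 * dt * ftot[k];
    for (int k = 0; k < dim; ++k) x[k] += 0.5 * dt * v[k];
    if (friction > 0) {
      for (int k = 0; k < dim; ++k) v[k] = c1 * v[k] + c2 * norm_rand();
    }
    for (int k = 0; k < dim; ++k) x[k] += 0.5 * dt * v[k];
    s_now = total_force(x, ftot.data(), &bh, &zh);
    for (int k = 0; k < dim; ++k) v[k] += 0.5 * dt * ftot[k];
    if (!std::isfinite(x[0]))
      stop("sampling diverged at step %d; reduce dt", step);

    if (use_metad && stride > 0 && step % stride == 0) {
      // well-tempered deposition at the current CV value
      double vb_here = bias_value(bias, smin, ds, ns, s_now, nullptr);
      double h = h0;
      if (R_finite(bias_factor))
        h = h0 * std::exp(-vb_here / ((bias_factor - 1.0) * kT));
      for (int i = 0; i < ns; ++i) {
        double si = smin + i * ds;
        double u = (si - s_now) / sigma_s;
        if (std::fabs(u) < 6.0) bias[i] += h * std::exp(-0.5 * u * u);
      }
      hill_t.push_back(step * dt);
      hill_c.push_back(s_now);
      hill_h.push_back(h);
    }
    if (step % record_stride == 0 && irec < n_rec) {
      traj(irec, 0) = step * dt;
      for (int k = 0; k < dim; ++k) traj(irec, 1 + k) = x[k];
      traj(irec, dim + 1) = s_now;
      traj(irec, dim + 2) = bh;
      ztraj[irec] = zh;
      ++irec;
    }
  }

  NumericMatrix hills(hill_t.size(), 3);
  for (size_t i = 0; i < hill_t.size(); ++i) {
    hills(i, 0) = hill_t[i]; hills(i, 1) = hill_c[i]; hills(i, 2) = hill_h[i];
  }
  return List::create(_["traj"] = traj,
                      _["z"] = NumericVector(ztraj.begin(), ztraj.begin() + irec),
                      _["hills"] = hills,
                      _["bias_grid"] = NumericVector(bias.begin(), bias.end()),
                      _["n_recorded"] = irec);
}
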