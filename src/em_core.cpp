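// Compiled cores for population simulation: Euler-Maruyama evolution and
// deterministic relaxation over the built-in polynomial families.
// Family ids: 1 = elliptic umbilic (and box2_example, flip_with_cusp),
// 2 = cusp1d, 3 = dual_cusp1d.

#include <Rcpp.h>
using namespace Rcpp;

static inline void grad_family(int fam, double x, double y,
                               double a, double b,
                               double &gx, double &gy) {
  switch (fam) {
  case 1:  // x^3 - 2xy^2 - 0.4x^2 + ax + by + (x^4+y^4)/4
    gx = 3.0 * x * x - 2.0 * y * y - 0.8 * x + a + x * x * x;
    gy = -4.0 * x * y + b + y * y * y;
    break;
  case 2:  // x^4/4 + a x^2/2 + b x + y^2/2
    gx = x * x * x + a * x + b;
    gy = y;
    break;
  case 3:  // x^6/6 - x^4/4 + a x^2/2 + b x + y^2/2
    gx = x * x * x * x * x - x * x * x + a * x + b;
    gy = y;
    break;
  default:
    gx = gy = 0.0;
  }
}

// [[Rcpp::export]]
List cpp_sde_population(int fam, NumericMatrix theta_path,
                        NumericMatrix X0, double dt, double sigma,
                        IntegerVector obs_steps, NumericMatrix Ginv,
                        NumericVector box_centre, NumericVector box_half) {
  int n = X0.nrow();
  int n_steps = theta_path.nrow();
  int n_obs = obs_steps.size();
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = X0(i, 0); y[i] = X0(i, 1); }
  double g11 = Ginv(0, 0), g12 = Ginv(0, 1), g21 = Ginv(1, 0),
         g22 = Ginv(1, 1);
  double sq = std::sqrt(dt) * sigma;
  List out(n_obs);
  int oi = 0;
  while (oi < n_obs && obs_steps[oi] == 0) {
    NumericMatrix snap(n, 2);
    for (int i = 0; i < n; ++i) { snap(i, 0) = x[i]; snap(i, 1) = y[i]; }
    out[oi++] = snap;
  }
  RNGScope scope;
  double cx = box_centre[0], cy = box_centre[1];
  double hx = 2.0 * box_half[0], hy = 2.0 * box_half[1];
  for (int s = 1; s <= n_steps; ++s) {
    double a = theta_path(s - 1, 0), b = theta_path(s - 1, 1);
    for (int i = 0; i < n; ++i) {
      double gx, gy;
      grad_family(fam, x[i], y[i], a, b, gx, gy);
      double vx = -(g11 * gx + g12 * gy);
      double vy = -(g21 * gx + g22 * gy);
      x[i] += dt * vx;
      y[i] += dt * vy;
      if (sq > 0.0) {
        x[i] += sq * norm_rand();
        y[i] += sq * norm_rand();
      }
      // clamp runaway cells to twice the domain box (escape guard)
      if (x[i] - cx > hx) x[i] = cx + hx;
      if (cx - x[i] > hx) x[i] = cx - hx;
      if (y[i] - cy > hy) y[i] = cy + hy;
      if (cy - y[i] > hy) y[i] = cy - hy;
    }
    while (oi < n_obs && obs_steps[oi] == s) {
      NumericMatrix snap(n, 2);
      for (int i = 0; i < n; ++i) { snap(i, 0) = x[i]; snap(i, 1) = y[i]; }
      out[oi++] = snap;
    }
  }
  while (oi < n_obs) {
    NumericMatrix snap(n, 2);
    for (int i = 0; i < n; ++i) { snap(i, 0) = x[i]; snap(i, 1) = y[i]; }
    out[oi++] = snap;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_relax(int fam, NumericMatrix X, NumericVector theta,
                        double dt, int max_steps, double conv_tol,
                        NumericMatrix A, double attr_tol,
                        NumericMatrix Ginv) {
  int n = X.nrow();
  int na = A.nrow();
  double a = theta[0], b = theta[1];
  double g11 = Ginv(0, 0), g12 = Ginv(0, 1), g21 = Ginv(1, 0),
         g22 = Ginv(1, 1);
  NumericMatrix out(clone(X));
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;
  double tol2 = attr_tol * attr_tol;
  std::vector<double> vxs, vys;
  for (int s = 1; s <= max_steps && !active.empty(); ++s) {
    vxs.assign(active.size(), 0.0);
    vys.assign(active.size(), 0.0);
    double max_sp = 0.0;
    for (size_t k = 0; k < active.size(); ++k) {
      int i = active[k];
      double gx, gy;
      grad_family(fam, out(i, 0), out(i, 1), a, b, gx, gy);
      vxs[k] = -(g11 * gx + g12 * gy);
      vys[k] = -(g21 * gx + g22 * gy);
      double sp = std::sqrt(vxs[k] * vxs[k] + vys[k] * vys[k]);
      if (sp > max_sp) max_sp = sp;
    }
    if (max_sp < conv_tol) break;
    for (size_t k = 0; k < active.size(); ++k) {
      int i = active[k];
      double sp = std::sqrt(vxs[k] * vxs[k] + vys[k] * vys[k]);
      double fac = 1.0;
      if (sp * dt > 0.2) fac = 0.2 / (sp * dt);
      out(i, 0) += dt * fac * vxs[k];
      out(i, 1) += dt * fac * vys[k];
    }
    if (na > 0 && s % 25 == 0) {
      std::vector<int> still;
      still.reserve(active.size());
      for (size_t k = 0; k < active.size(); ++k) {
        int i = active[k];
        double dmin2 = R_PosInf;
        for (int q = 0; q < na; ++q) {
          double dx = out(i, 0) - A(q, 0), dy = out(i, 1) - A(q, 1);
          double d2 = dx * dx + dy * dy;
          if (d2 < dmin2) dmin2 = d2;
        }
        if (dmin2 >= tol2) still.push_back(i);
      }
      active.swap(still);
    }
  }
  return out;
}
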