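// Adaptive ODE integration for the Michaelis-Menten mass-action system
// and its one-dimensional QSS reductions.
//
// Two steppers are provided:
//   * Dormand-Prince 5(4) with FSAL (nonstiff default), and
//   * a Rosenbrock 2(3) pair (Shampine coefficients) with the analytic
//     2x2 Jacobian, L-stable, for stiff parameter regimes where the
//     fast eigenvalue times the horizon makes an explicit method
//     impractical.
// Output is the sequence of accepted steps with the vector field at
// each node, which supports cubic Hermite interpolation in R (dense
// output for crossing detection and error metrics).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

enum Model {
  MODEL_FULL = 0,
  MODEL_SQSSA = 1,
  MODEL_SLOW_PRODUCT = 2,
  MODEL_KUMAR_JOSIC = 3,
  MODEL_CALDER_SIEGEL = 4,
  MODEL_RQSSA_OUTER = 5,
  MODEL_RQSSA_INNER = 6
};

struct Pars {
  double k1, km1, k2, e0, KM, KS, m;
};

static inline void rhs(int model, const Pars &p, const double *y,
                       double *dy) {
  switch (model) {
  case MODEL_FULL: {
    double s = y[0], c = y[1];
    double bind = p.k1 * (p.e0 - c) * s;
    dy[0] = -bind + p.km1 * c;
    dy[1] = bind - (p.km1 + p.k2) * c;
    break;
  }
  case MODEL_SQSSA: {
    double s = y[0];
    dy[0] = -p.k2 * p.e0 * s / (p.KM + s);
    break;
  }
  case MODEL_SLOW_PRODUCT: {
    double s = y[0], q = p.KS + s;
    dy[0] = -p.k2 * p.e0 * s * q / (p.KS * p.e0 + q * q);
    break;
  }
  case MODEL_KUMAR_JOSIC: {
    double s = y[0], q = p.KM + s;
    dy[0] = -p.k2 * p.e0 * s * q / (p.KM * p.e0 + q * q);
    break;
  }
  case MODEL_CALDER_SIEGEL: {
    double s = y[0];
    dy[0] = (p.e0 <= 0.0) ? 0.0
      : -(p.e0 * s / (p.e0 + p.m * s)) * (p.k1 * p.e0 - p.km1 * p.m);
    break;
  }
  case MODEL_RQSSA_OUTER:
    dy[0] = -p.k2 * p.e0;
    break;
  case MODEL_RQSSA_INNER:
    dy[0] = -p.k2 * y[0];
    break;
  }
}

// Analytic Jacobian of the full planar system (used by the Rosenbrock
// stepper; reductions are integrated with the explicit pair).
static inline void jac_full(const Pars &p, const double *y, double *J) {
  double s = y[0], c = y[1];
  J[0] = -p.k1 * (p.e0 - c);          // d ds/ds
  J[1] = p.k1 * s + p.km1;            // d ds/dc
  J[2] = p.k1 * (p.e0 - c);           // d dc/ds
  J[3] = -(p.k1 * s + p.km1 + p.k2);  // d dc/dc
}

static inline double err_norm(int dim, const double *e, const double *y0,
                              const double *y1, double rtol, double atol) {
  double sum = 0.0;
  for (int i = 0; i < dim; ++i) {
    double sc = atol + rtol * std::max(std::fabs(y0[i]), std::fabs(y1[i]));
    double r = e[i] / sc;
    sum += r * r;
  }
  return std::sqrt(sum / dim);
}

struct Out {
  std::vector<double> t;
  std::vector<double> y;     // dim-major by row: y[i*dim + j]
  std::vector<double> f;
  std::vector<double> dense; // 5 coeffs per component per step (DP45)
  int status = 0;            // 0 ok, 1 max steps, 2 step underflow
};

static void push(Out &out, int dim, double t, const double *y,
                 const double *f) {
  out.t.push_back(t);
  for (int j = 0; j < dim; ++j) out.y.push_back(y[j]);
  for (int j = 0; j < dim; ++j) out.f.push_back(f[j]);
}

// ---------------------------------------------------------------- DP45
static void dp45(int model, const Pars &p, int dim, double *y, double t0,
                 double tmax, double rtol, double atol, double y_stop,
                 double max_steps, Out &out) {
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
    c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
    a63 = 46732.0 / 5247, a64 = 49.0 / 176, a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113,
    b4 = 125.0 / 192, b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 35.0 / 384 - 5179.0 / 57600,
    e3 = 500.0 / 1113 - 7571.0 / 16695, e4 = 125.0 / 192 - 393.0 / 640,
    e5 = -2187.0 / 6784 + 92097.0 / 339200, e6 = 11.0 / 84 - 187.0 / 2100,
    e7 = -1.0 / 40;

  double k1v[2], k2v[2], k3v[2], k4v[2], k5v[2], k6v[2], k7v[2];
  double ytmp[2], ynew[2], err[2];
  double t = t0;

  rhs(model, p, y, k1v);
  push(out, dim, t, y, k1v);

  // initial step-size guess from the magnitudes of y and f
  double h = (tmax - t0);
  for (int j = 0; j < dim; ++j) {
    double sc = atol + rtol * std::fabs(y[j]);
    if (std::fabs(k1v[j]) > 1e-300)
      h = std::min(h, 0.01 * (std::fabs(y[j]) + sc) / std::fabs(k1v[j]));
  }
  h = std::max(h, 1e-12 * (tmax - t0));

  double steps = 0;
  while (t < tmax) {
    if (++steps > max_steps) { out.status = 1; return; }
    if (h < 1e-14 * std::max(1.0, std::fabs(t))) { out.status = 2; return; }
    if (t + h > tmax) h = tmax - t;

    for (int j = 0; j < dim; ++j) ytmp[j] = y[j] + h * a21 * k1v[j];
    rhs(model, p, ytmp, k2v);
    for (int j = 0; j < dim; ++j)
      ytmp[j] = y[j] + h * (a31 * k1v[j] + a32 * k2v[j]);
    rhs(model, p, ytmp, k3v);
    for (int j = 0; j < dim; ++j)
      ytmp[j] = y[j] + h * (a41 * k1v[j] + a42 * k2v[j] + a43 * k3v[j]);
    rhs(model, p, ytmp, k4v);
    for (int j = 0; j < dim; ++j)
      ytmp[j] = y[j] + h * (a51 * k1v[j] + a52 * k2v[j] + a53 * k3v[j] +
                            a54 * k4v[j]);
    rhs(model, p, ytmp, k5v);
    for (int j = 0; j < dim; ++j)
      ytmp[j] = y[j] + h * (a61 * k1v[j] + a62 * k2v[j] + a63 * k3v[j] +
                            a64 * k4v[j] + a65 * k5v[j]);
    rhs(model, p, ytmp, k6v);
    for (int j = 0; j < dim; ++j)
      ynew[j] = y[j] + h * (b1 * k1v[j] + b3 * k3v[j] + b4 * k4v[j] +
                            b5 * k5v[j] + b6 * k6v[j]);
    rhs(model, p, ynew, k7v);
    for (int j = 0; j < dim; ++j)
      err[j] = h * (e1 * k1v[j] + e3 * k3v[j] + e4 * k4v[j] +
                    e5 * k5v[j] + e6 * k6v[j] + e7 * k7v[j]);

    double en = err_norm(dim, err, y, ynew, rtol, atol);
    if (en <= 1.0) {
      // 4th-order dense-output coefficients (Hairer's contd5)
      static const double d1 = -12715105075.0 / 11282082432.0,
        d3 = 87487479700.0 / 32700410799.0,
        d4 = -10690763975.0 / 1880347072.0,
        d5 = 701980252875.0 / 199316789632.0,
        d6 = -1453857185.0 / 822651844.0,
        d7 = 69997945.0 / 29380423.0;
      for (int j = 0; j < dim; ++j) {
        double dy = ynew[j] - y[j];
        double r1 = y[j];
        double r2 = dy;
        double r3 = h * k1v[j] - dy;
        double r4 = dy - h * k7v[j] - r3;
        double r5 = h * (d1 * k1v[j] + d3 * k3v[j] + d4 * k4v[j] +
                         d5 * k5v[j] + d6 * k6v[j] + d7 * k7v[j]);
        out.dense.push_back(r1); out.dense.push_back(r2);
        out.dense.push_back(r3); out.dense.push_back(r4);
        out.dense.push_back(r5);
      }
      t += h;
      for (int j = 0; j < dim; ++j) { y[j] = ynew[j]; k1v[j] = k7v[j]; }
      push(out, dim, t, y, k1v);
      if (y[0] <= y_stop) return;
      double fac = (en > 0) ? 0.9 * std::pow(en, -0.2) : 5.0;
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      h *= std::max(0.2, 0.9 * std::pow(en, -0.2));
    }
    (void)c2; (void)c3; (void)c4; (void)c5;
  }
}

// --------------------------------------------------------------- ROS23
// Shampine's Rosenbrock pair (the ode23s scheme), autonomous form.
static void ros23(int model, const Pars &p, int dim, double *y, double t0,
                  double tmax, double rtol, double atol, double y_stop,
                  double max_steps, Out &out) {
  const double d = 1.0 / (2.0 + std::sqrt(2.0));
  const double e32 = 6.0 + std::sqrt(2.0);

  double f0[2], f1[2], f2[2], k1v[2], k2v[2], k3v[2];
  double ytmp[2], ynew[2], err[2], J[4], W[4];
  double t = t0;

  rhs(model, p, y, f0);
  push(out, dim, t, y, f0);

  double h = (tmax - t0) * 1e-6;
  for (int j = 0; j < dim; ++j) {
    double sc = atol + rtol * std::fabs(y[j]);
    if (std::fabs(f0[j]) > 1e-300)
      h = std::min(h, 0.01 * (std::fabs(y[j]) + sc) / std::fabs(f0[j]));
  }
  h = std::max(h, 1e-13 * (tmax - t0));

  double steps = 0;
  while (t < tmax) {
    if (++steps > max_steps) { out.status = 1; return; }
    if (h < 1e-14 * std::max(1.0, std::fabs(t))) { out.status = 2; return; }
    if (t + h > tmax) h = tmax - t;

    jac_full(p, y, J);
    // W = I - h*d*J; direct 2x2 (or 1x1) solve
    double hd = h * d;
    bool ok = true;
    double det = 1.0, w00 = 1.0, w01 = 0.0, w10 = 0.0, w11 = 1.0;
    if (dim == 2) {
      w00 = 1.0 - hd * J[0]; w01 = -hd * J[1];
      w10 = -hd * J[2];      w11 = 1.0 - hd * J[3];
      det = w00 * w11 - w01 * w10;
      if (det == 0.0 || !std::isfinite(det)) ok = false;
    } else {
      w00 = 1.0 - hd * J[0];
      det = w00;
      if (det == 0.0 || !std::isfinite(det)) ok = false;
    }
    if (!ok) { h *= 0.5; continue; }
    W[0] = w00; W[1] = w01; W[2] = w10; W[3] = w11;

    auto solve = [&](const double *b, double *x) {
      if (dim == 2) {
        x[0] = (W[3] * b[0] - W[1] * b[1]) / det;
        x[1] = (W[0] * b[1] - W[2] * b[0]) / det;
      } else {
        x[0] = b[0] / det;
      }
    };

    solve(f0, k1v);
    for (int j = 0; j < dim; ++j) ytmp[j] = y[j] + 0.5 * h * k1v[j];
    rhs(model, p, ytmp, f1);
    double b2[2];
    for (int j = 0; j < dim; ++j) b2[j] = f1[j] - k1v[j];
    solve(b2, k2v);
    for (int j = 0; j < dim; ++j) k2v[j] += k1v[j];
    for (int j = 0; j < dim; ++j) ynew[j] = y[j] + h * k2v[j];
    rhs(model, p, ynew, f2);
    double b3v[2];
    for (int j = 0; j < dim; ++j)
      b3v[j] = f2[j] - e32 * (k2v[j] - f1[j]) - 2.0 * (k1v[j] - f0[j]);
    solve(b3v, k3v);
    for (int j = 0; j < dim; ++j)
      err[j] = (h / 6.0) * (k1v[j] - 2.0 * k2v[j] + k3v[j]);

    double en = err_norm(dim, err, y, ynew, rtol, atol);
    if (en <= 1.0) {
      t += h;
      for (int j = 0; j < dim; ++j) { y[j] = ynew[j]; f0[j] = f2[j]; }
      push(out, dim, t, y, f0);
      if (y[0] <= y_stop) return;
      double fac = (en > 0) ? 0.9 * std::pow(en, -1.0 / 3.0) : 5.0;
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      h *= std::max(0.2, 0.9 * std::pow(en, -1.0 / 3.0));
    }
  }
}

// [[Rcpp::export(name = ".ode_solve")]]
List ode_solve(int model, NumericVector pars, NumericVector y0, double t0,
               double tmax, double rtol, double atol, double y_stop,
               std::string method, double max_steps) {
  Pars p;
  p.k1 = pars["k1"]; p.km1 = pars["k_neg1"]; p.k2 = pars["k2"];
  p.e0 = pars["e0"];
  p.KM = (p.km1 + p.k2) / p.k1;
  p.KS = p.km1 / p.k1;
  p.m = pars.containsElementNamed("m") ? double(pars["m"]) : NA_REAL;

  int dim = y0.size();
  if (model == MODEL_FULL && dim != 2)
    stop("full model requires a 2-dimensional state");
  if (model != MODEL_FULL && dim != 1)
    stop("reduced models require a scalar state");

  double y[2];
  for (int j = 0; j < dim; ++j) y[j] = y0[j];

  Out out;
  if (method == "ros23") {
    if (model != MODEL_FULL)
      stop("ros23 is implemented for the full model only");
    ros23(model, p, dim, y, t0, tmax, rtol, atol, y_stop, max_steps, out);
  } else if (method == "dp45") {
    dp45(model, p, dim, y, t0, tmax, rtol, atol, y_stop, max_steps, out);
  } else {
    stop("unknown method '%s'", method.c_str());
  }

  int n = out.t.size();
  NumericMatrix ym(n, dim), fm(n, dim);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < dim; ++j) {
      ym(i, j) = out.y[i * dim + j];
      fm(i, j) = out.f[i * dim + j];
    }
  int ncoef = 5 * dim;
  int nd = out.dense.size() / ncoef;
  NumericMatrix dm(nd, ncoef);
  for (int i = 0; i < nd; ++i)
    for (int j = 0; j < ncoef; ++j)
      dm(i, j) = out.dense[i * ncoef + j];
  return List::create(_["t"] = NumericVector(out.t.begin(), out.t.end()),
                      _["y"] = ym, _["f"] = fm, _["dense"] = dm,
                      _["status"] = out.status, _["n_steps"] = n - 1);
}
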