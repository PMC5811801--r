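#include <Rcpp.h>
using namespace Rcpp;

// Third-order SCRF dynamics: x''' = -th1*x'' - th2*x' - th3*x - gain*u(t - th4).
// State y = (x, x', x''). Input u sampled on a uniform grid with step dt,
// evaluated by linear interpolation; held at its boundary values outside the
// recorded span (the delay line th4 can push lookups past either end).

static inline double interp_u(const double* u, int n, double dt, double t) {
  double pos = t / dt;
  if (pos <= 0.0) return u[0];
  if (pos >= n - 1) return u[n - 1];
  int i = (int)pos;
  double w = pos - i;
  return u[i] * (1.0 - w) + u[i + 1] * w;
}

static inline void deriv(double th1, double th2, double th3, double gain,
                         double uu, const double* y, double* dy) {
  dy[0] = y[1];
  dy[1] = y[2];
  dy[2] = -th1 * y[2] - th2 * y[1] - th3 * y[0] - gain * uu;
}

// Fixed-step RK4 with `substeps` internal steps per output sample.
// [[Rcpp::export]]
NumericVector scrf_rk4_cpp(NumericVector u, double dt,
                           double th1, double th2, double th3, double th4,
                           double gain, int substeps) {
  int n = u.size();
  NumericVector x(n);
  if (n == 0) return x;
  const double* up = u.begin();
  double y[3] = {0.0, 0.0, 0.0};
  double k1[3], k2[3], k3[3], k4[3], tmp[3];
  double h = dt / substeps;
  double t = 0.0;
  x[0] = 0.0;
  for (int i = 1; i < n; ++i) {
    for (int s = 0; s < substeps; ++s) {
      double u0 = interp_u(up, n, dt, t - th4);
      double um = interp_u(up, n, dt, t + 0.5 * h - th4);
      double u1 = interp_u(up, n, dt, t + h - th4);
      deriv(th1, th2, th3, gain, u0, y, k1);
      for (int j = 0; j < 3; ++j) tmp[j] = y[j] + 0.5 * h * k1[j];
      deriv(th1, th2, th3, gain, um, tmp, k2);
      for (int j = 0; j < 3; ++j) tmp[j] = y[j] + 0.5 * h * k2[j];
      deriv(th1, th2, th3, gain, um, tmp, k3);
      for (int j = 0; j < 3; ++j) tmp[j] = y[j] + h * k3[j];
      deriv(th1, th2, th3, gain, u1, tmp, k4);
      for (int j = 0; j < 3; ++j)
        y[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      t += h;
    }
    x[i] = y[0];
  }
  return x;
}

// Response to a unit Dirac impulse at t = 0 (before the th4 delay line):
// integrating the ODE across the impulse gives the jump condition
// x(0) = x'(0) = 0, x''(0) = -gain. The homogeneous system is then
// integrated with RK4; the caller applies the th4 shift.
// [[Rcpp::export]]
NumericVector scrf_impulse_cpp(int n, double dt,
                               double th1, double th2, double th3,
                               double gain, int substeps) {
  NumericVector x(n);
  if (n == 0) return x;
  double y[3] = {0.0, 0.0, -gain};
  double k1[3], k2[3], k3[3], k4[3], tmp[3];
  double h = dt / substeps;
  x[0] = 0.0;
  for (int i = 1; i < n; ++i) {
    for (int s = 0; s < substeps; ++s) {
      deriv(th1, th2, th3, 0.0, 0.0, y, k1);
      for (int j = 0; j < 3; ++j) tmp[j] = y[j] + 0.5 * h * k1[j];
      deriv(th1, th2, th3, 0.0, 0.0, tmp, k2);
      for (int j = 0; j < 3; ++j) tmp[j] = y[j] + 0.5 * h * k2[j];
      deriv(th1, th2, th3, 0.0, 0.0, tmp, k3);
      for (int j = 0; j < 3; ++j) tmp[j] = y[j] + h * k3[j];
      deriv(th1, th2, th3, 0.0, 0.0, tmp, k4);
      for (int j = 0; j < 3; ++j)
        y[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    }
    x[i] = y[0];
  }
  return x;
}
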