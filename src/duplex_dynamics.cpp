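#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Right-hand side of the coupled base-pendulum equations.
//
// State per base pair i: angles phi1[i], phi2[i] (rad) and angular
// velocities v1[i], v2[i] (rad/s). Chain-1 rest angle is 0, chain-2 rest
// angle is pi. Torques:
//   backbone torsion  K_j[i] * (phi_{i-1} - 2 phi_i + phi_{i+1})
//                     (one-neighbour form at i = 1 and i = n; absent at n = 1)
//   pair coupling     chain 1: -k12 R1 (R1+R2) sin(phi1) - k12 R1 R2 sin(phi1 - phi2)
//                     chain 2, variant 0 (as_printed):
//                              +k12 R1 (R1+R2) sin(phi2) - k12 R1 R2 sin(phi1 - phi2)
//                     chain 2, variant 1 (potential_consistent):
//                              -k12 R2 (R1+R2) sin(phi2) + k12 R1 R2 sin(phi1 - phi2)
//   external          -beta_j[i] * v_j[i] + F0 cos(omega t)  (same drive on every pendulum)
//
// Chain-2 sines are computed through the deviation psi2 = phi2 - pi:
// sin(phi2) = -sin(psi2) and sin(phi1 - phi2) = -sin(phi1 - psi2). This is
// an exact identity, and makes the equilibrium state (phi1 = 0, phi2 = pi)
// an exact floating-point fixed point of the undriven system (sin of an
// exact 0 argument, instead of sin(pi) ~ 1.2e-16).

struct DuplexCoefs {
  int n;
  const double *I1, *I2, *K1, *K2, *R1, *R2, *B1, *B2, *k12;
  double F0, omega;
  int variant; // 0 = as_printed, 1 = potential_consistent
};

static inline void duplex_accel(const DuplexCoefs &c,
                                const double *phi1, const double *phi2,
                                const double *v1, const double *v2,
                                double t, double *a1, double *a2) {
  const int n = c.n;
  const double drive = c.F0 * std::cos(c.omega * t);
  for (int i = 0; i < n; ++i) {
    double lap1, lap2;
    if (n == 1) {
      lap1 = 0.0;
      lap2 = 0.0;
    } else if (i == 0) {
      lap1 = c.K1[0] * (phi1[1] - phi1[0]);
      lap2 = c.K2[0] * (phi2[1] - phi2[0]);
    } else if (i == n - 1) {
      lap1 = c.K1[i] * (phi1[i - 1] - phi1[i]);
      lap2 = c.K2[i] * (phi2[i - 1] - phi2[i]);
    } else {
      lap1 = c.K1[i] * (phi1[i - 1] - 2.0 * phi1[i] + phi1[i + 1]);
      lap2 = c.K2[i] * (phi2[i - 1] - 2.0 * phi2[i] + phi2[i + 1]);
    }
    const double psi2 = phi2[i] - M_PI;
    const double s1 = std::sin(phi1[i]);
    const double s2 = std::sin(psi2);              // sin(phi2)        = -s2
    const double sx = std::sin(phi1[i] - psi2);    // sin(phi1 - phi2) = -sx
    const double k = c.k12[i];
    const double r1 = c.R1[i], r2 = c.R2[i];

    // chain 1: -k R1(R1+R2) sin(phi1) - k R1 R2 sin(phi1-phi2)
    const double pair1 = -k * r1 * (r1 + r2) * s1 + k * r1 * r2 * sx;
    double pair2;
    if (c.variant == 0) {
      // +k R1(R1+R2) sin(phi2) - k R1 R2 sin(phi1-phi2)
      pair2 = -k * r1 * (r1 + r2) * s2 + k * r1 * r2 * sx;
    } else {
      // -k R2(R1+R2) sin(phi2) + k R1 R2 sin(phi1-phi2)
      pair2 = k * r2 * (r1 + r2) * s2 - k * r1 * r2 * sx;
    }
    a1[i] = (lap1 + pair1 - c.B1[i] * v1[i] + drive) / c.I1[i];
    a2[i] = (lap2 + pair2 - c.B2[i] * v2[i] + drive) / c.I2[i];
  }
}

static DuplexCoefs make_coefs(const NumericVector &I1, const NumericVector &I2,
                              const NumericVector &K1, const NumericVector &K2,
                              const NumericVector &R1, const NumericVector &R2,
                              const NumericVector &B1, const NumericVector &B2,
                              const NumericVector &k12,
                              double F0, double omega, int variant) {
  DuplexCoefs c;
  c.n = I1.size();
  c.I1 = I1.begin(); c.I2 = I2.begin();
  c.K1 = K1.begin(); c.K2 = K2.begin();
  c.R1 = R1.begin(); c.R2 = R2.begin();
  c.B1 = B1.begin(); c.B2 = B2.begin();
  c.k12 = k12.begin();
  c.F0 = F0; c.omega = omega; c.variant = variant;
  return c;
}

// [[Rcpp::export]]
List rhs_cpp(NumericVector phi1, NumericVector phi2,
             NumericVector v1, NumericVector v2, double t,
             NumericVector I1, NumericVector I2,
             NumericVector K1, NumericVector K2,
             NumericVector R1, NumericVector R2,
             NumericVector B1, NumericVector B2,
             NumericVector k12,
             double F0, double omega, int variant) {
  DuplexCoefs c = make_coefs(I1, I2, K1, K2, R1, R2, B1, B2, k12,
                             F0, omega, variant);
  NumericVector a1(c.n), a2(c.n);
  duplex_accel(c, phi1.begin(), phi2.begin(), v1.begin(), v2.begin(), t,
               a1.begin(), a2.begin());
  return List::create(_["dphi1"] = clone(v1), _["dphi2"] = clone(v2),
                      _["dv1"] = a1, _["dv2"] = a2);
}

// One classical RK4 step of the full 4n-component first-order system.
struct RK4Work {
  std::vector<double> p1, p2, u1, u2;       // stage states
  std::vector<double> a1, a2;               // stage accelerations
  std::vector<double> sp1, sp2, sv1, sv2;   // accumulated increments
  explicit RK4Work(int n)
      : p1(n), p2(n), u1(n), u2(n), a1(n), a2(n),
        sp1(n), sp2(n), sv1(n), sv2(n) {}
};

static void rk4_advance(const DuplexCoefs &c, double t, double dt,
                        double *phi1, double *phi2, double *v1, double *v2,
                        RK4Work &w) {
  const int n = c.n;
  // stage 1 at (t, y)
  duplex_accel(c, phi1, phi2, v1, v2, t, w.a1.data(), w.a2.data());
  for (int i = 0; i < n; ++i) {
    w.sp1[i] = v1[i]; w.sp2[i] = v2[i];
    w.sv1[i] = w.a1[i]; w.sv2[i] = w.a2[i];
    w.p1[i] = phi1[i] + 0.5 * dt * v1[i];
    w.p2[i] = phi2[i] + 0.5 * dt * v2[i];
    w.u1[i] = v1[i] + 0.5 * dt * w.a1[i];
    w.u2[i] = v2[i] + 0.5 * dt * w.a2[i];
  }
  // stage 2 at (t + dt/2)
  duplex_accel(c, w.p1.data(), w.p2.data(), w.u1.data(), w.u2.data(),
               t + 0.5 * dt, w.a1.data(), w.a2.data());
  for (int i = 0; i < n; ++i) {
    w.sp1[i] += 2.0 * w.u1[i]; w.sp2[i] += 2.0 * w.u2[i];
    w.sv1[i] += 2.0 * w.a1[i]; w.sv2[i] += 2.0 * w.a2[i];
    const double q1 = w.u1[i], q2 = w.u2[i];
    w.p1[i] = phi1[i] + 0.5 * dt * q1;
    w.p2[i] = phi2[i] + 0.5 * dt * q2;
    w.u1[i] = v1[i] + 0.5 * dt * w.a1[i];
    w.u2[i] = v2[i] + 0.5 * dt * w.a2[i];
  }
  // stage 3 at (t + dt/2)
  duplex_accel(c, w.p1.data(), w.p2.data(), w.u1.data(), w.u2.data(),
               t + 0.5 * dt, w.a1.data(), w.a2.data());
  for (int i = 0; i < n; ++i) {
    w.sp1[i] += 2.0 * w.u1[i]; w.sp2[i] += 2.0 * w.u2[i];
    w.sv1[i] += 2.0 * w.a1[i]; w.sv2[i] += 2.0 * w.a2[i];
    w.p1[i] = phi1[i] + dt * w.u1[i];
    w.p2[i] = phi2[i] + dt * w.u2[i];
    w.u1[i] = v1[i] + dt * w.a1[i];
    w.u2[i] = v2[i] + dt * w.a2[i];
  }
  // stage 4 at (t + dt)
  duplex_accel(c, w.p1.data(), w.p2.data(), w.u1.data(), w.u2.data(),
               t + dt, w.a1.data(), w.a2.data());
  const double h6 = dt / 6.0;
  for (int i = 0; i < n; ++i) {
    phi1[i] += h6 * (w.sp1[i] + w.u1[i]);
    phi2[i] += h6 * (w.sp2[i] + w.u2[i]);
    v1[i] += h6 * (w.sv1[i] + w.a1[i]);
    v2[i] += h6 * (w.sv2[i] + w.a2[i]);
  }
}

// [[Rcpp::export]]
List rk4_step_cpp(NumericVector phi1, NumericVector phi2,
                  NumericVector v1, NumericVector v2,
                  double t, double dt,
                  NumericVector I1, NumericVector I2,
                  NumericVector K1, NumericVector K2,
                  NumericVector R1, NumericVector R2,
                  NumericVector B1, NumericVector B2,
                  NumericVector k12,
                  double F0, double omega, int variant) {
  DuplexCoefs c = make_coefs(I1, I2, K1, K2, R1, R2, B1, B2, k12,
                             F0, omega, variant);
  NumericVector q1 = clone(phi1), q2 = clone(phi2);
  NumericVector u1 = clone(v1), u2 = clone(v2);
  RK4Work w(c.n);
  rk4_advance(c, t, dt, q1.begin(), q2.begin(), u1.begin(), u2.begin(), w);
  for (int i = 0; i < c.n; ++i) {
    if (!std::isfinite(q1[i]) || !std::isfinite(q2[i]) ||
        !std::isfinite(u1[i]) || !std::isfinite(u2[i]))
      stop("non-finite state after RK4 step at t = %g s", t + dt);
  }
  return List::create(_["t"] = t + dt, _["phi1"] = q1, _["phi2"] = q2,
                      _["v1"] = u1, _["v2"] = u2);
}

// Fixed-step RK4 integration with strided recording. Chain-mean angle
// series are always recorded; full per-site snapshots only on request.
// [[Rcpp::export]]
List integrate_cpp(NumericVector phi1_0, NumericVector phi2_0,
                   NumericVector v1_0, NumericVector v2_0,
                   double t0,
                   NumericVector I1, NumericVector I2,
                   NumericVector K1, NumericVector K2,
                   NumericVector R1, NumericVector R2,
                   NumericVector B1, NumericVector B2,
                   NumericVector k12,
                   double F0, double omega, int variant,
                   double dt, int nsteps, int stride, bool record_full) {
  DuplexCoefs c = make_coefs(I1, I2, K1, K2, R1, R2, B1, B2, k12,
                             F0, omega, variant);
  const int n = c.n;
  std::vector<double> phi1(phi1_0.begin(), phi1_0.end());
  std::vector<double> phi2(phi2_0.begin(), phi2_0.end());
  std::vector<double> v1(v1_0.begin(), v1_0.end());
  std::vector<double> v2(v2_0.begin(), v2_0.end());
  RK4Work w(n);

  const int nrec = nsteps / stride + 1;
  NumericVector times(nrec), mean1(nrec), mean2(nrec);
  NumericMatrix M1, M2, W1, W2;
  if (record_full) {
    M1 = NumericMatrix(nrec, n); M2 = NumericMatrix(nrec, n);
    W1 = NumericMatrix(nrec, n); W2 = NumericMatrix(nrec, n);
  }

  int rec = 0;
  for (int step = 0; step <= nsteps; ++step) {
    const double t = t0 + step * dt;
    if (step % stride == 0 && rec < nrec) {
      double s1 = 0.0, s2 = 0.0;
      bool finite = true;
      double maxabs = 0.0;
      for (int i = 0; i < n; ++i) {
        s1 += phi1[i]; s2 += phi2[i];
        if (!std::isfinite(phi1[i]) || !std::isfinite(phi2[i]) ||
            !std::isfinite(v1[i]) || !std::isfinite(v2[i]))
          finite = false;
        const double a = std::max(std::fabs(phi1[i]), std::fabs(phi2[i]));
        if (a > maxabs) maxabs = a;
      }
      if (!finite)
        stop("integration blow-up: non-finite state at step %d (t = %g s), max |phi| so far = %g rad",
             step, t, maxabs);
      times[rec] = t;
      mean1[rec] = s1 / n;
      mean2[rec] = s2 / n;
      if (record_full) {
        for (int i = 0; i < n; ++i) {
          M1(rec, i) = phi1[i]; M2(rec, i) = phi2[i];
          W1(rec, i) = v1[i];   W2(rec, i) = v2[i];
        }
      }
      ++rec;
    }
    if (step == nsteps) break;
    rk4_advance(c, t, dt, phi1.data(), phi2.data(), v1.data(), v2.data(), w);
    if ((step & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
      _["times"] = times, _["mean_phi1"] = mean1, _["mean_phi2"] = mean2,
      _["final"] = List::create(
          _["t"] = t0 + nsteps * dt,
          _["phi1"] = NumericVector(phi1.begin(), phi1.end()),
          _["phi2"] = NumericVector(phi2.begin(), phi2.end()),
          _["v1"] = NumericVector(v1.begin(), v1.end()),
          _["v2"] = NumericVector(v2.begin(), v2.end())));
  if (record_full) {
    out["phi1"] = M1; out["phi2"] = M2; out["v1"] = W1; out["v2"] = W2;
  }
  return out;
}
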