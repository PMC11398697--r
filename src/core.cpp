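// Compiled core: the 1 kHz zero-order-hold closed loop (pendulum dynamics,
// classical RK4 substeps, built-in controller kinds) and the dynamic time
// warping cost used by the mode metric. Controller semantics mirror the R
// reference path in R/simulate.R exactly; the R tests cross-check the two.
#include <Rcpp.h>
using namespace Rcpp;

struct Params {
  double l, m1, m2, k1, k2, qe1, qe2, d1, d2, J1, J2;
};

static Params unpack(const NumericVector& p) {
  Params P;
  P.l = p["l1"]; // l1 == l2 throughout
  P.m1 = p["m1"]; P.m2 = p["m2"];
  P.k1 = p["k1"]; P.k2 = p["k2"];
  P.qe1 = p["qe1"]; P.qe2 = p["qe2"];
  P.d1 = p["d1"]; P.d2 = p["d2"];
  P.J1 = p["J1"]; P.J2 = p["J2"];
  return P;
}

// Joint accelerations for commanded motor-link angle theta (first spring
// pulls q1 toward theta, second spring pulls q2 toward its equilibrium).
static inline void accel_c(const Params& P, double q1, double q2,
                           double qd1, double qd2, double theta,
                           double& a1, double& a2) {
  const double c2 = cos(q2), s2 = sin(q2), l2 = P.l * P.l;
  const double M11 = P.J1 + P.J2 + 0.25 * l2 * (P.m1 + 5.0 * P.m2 + 4.0 * P.m2 * c2);
  const double M12 = P.J2 + 0.25 * l2 * P.m2 * (1.0 + 2.0 * c2);
  const double M22 = P.J2 + 0.25 * l2 * P.m2;
  const double h = -0.5 * l2 * P.m2 * s2;
  // C(q, qd) qd with C = h * [[qd2, qd1+qd2], [-qd1, 0]]
  const double cor1 = h * qd2 * qd1 + h * (qd1 + qd2) * qd2;
  const double cor2 = -h * qd1 * qd1;
  const double r1 = -cor1 - P.k1 * (q1 - theta) - P.d1 * qd1;
  const double r2 = -cor2 - P.k2 * (q2 - P.qe2) - P.d2 * qd2;
  const double det = M11 * M22 - M12 * M12;
  a1 = (M22 * r1 - M12 * r2) / det;
  a2 = (M11 * r2 - M12 * r1) / det;
}

// One classical RK4 step of length h with theta held constant.
static inline void rk4_step(const Params& P, double h, double theta,
                            double& q1, double& q2, double& qd1, double& qd2) {
  double a1, a2, b1, b2, c1, c2k, d1k, d2k;
  accel_c(P, q1, q2, qd1, qd2, theta, a1, a2);
  double q1b = q1 + 0.5 * h * qd1, q2b = q2 + 0.5 * h * qd2;
  double v1b = qd1 + 0.5 * h * a1, v2b = qd2 + 0.5 * h * a2;
  accel_c(P, q1b, q2b, v1b, v2b, theta, b1, b2);
  double q1c = q1 + 0.5 * h * v1b, q2c = q2 + 0.5 * h * v2b;
  double v1c = qd1 + 0.5 * h * b1, v2c = qd2 + 0.5 * h * b2;
  accel_c(P, q1c, q2c, v1c, v2c, theta, c1, c2k);
  double q1d = q1 + h * v1c, q2d = q2 + h * v2c;
  double v1d = qd1 + h * c1, v2d = qd2 + h * c2k;
  accel_c(P, q1d, q2d, v1d, v2d, theta, d1k, d2k);
  q1 += h / 6.0 * (qd1 + 2.0 * v1b + 2.0 * v1c + v1d);
  q2 += h / 6.0 * (qd2 + 2.0 * v2b + 2.0 * v2c + v2d);
  qd1 += h / 6.0 * (a1 + 2.0 * b1 + 2.0 * c1 + d1k);
  qd2 += h / 6.0 * (a2 + 2.0 * b2 + 2.0 * c2k + d2k);
}

enum CtrlKind { HOLD = 0, SINE = 1, BANGBANG = 2, RANDOM = 3, PARTICIPANT = 4 };

// [[Rcpp::export]]
List simulate_core(NumericVector par, List ctrl, double duration, double fs,
                   int nsub, NumericVector q0, NumericVector qd0) {
  const Params P = unpack(par);
  const int n = (int) std::lround(duration * fs) + 1;
  const double dt = 1.0 / fs, h = dt / nsub;
  const int kind = as<int>(ctrl["kind_code"]);
  NumericVector cp = ctrl["pars"];

  NumericVector t(n), theta(n), q1v(n), q2v(n), qd1v(n), qd2v(n), tau(n);
  double q1 = q0[0], q2 = q0[1], qd1 = qd0[0], qd2 = qd0[1];

  // controller state
  double th_prev = ctrl.containsElementNamed("theta0") ? as<double>(ctrl["theta0"]) : 0.0;
  // random excitation state
  double ramp = 0.0, romega = 0.0, next_reseed = -1.0;
  // participant state
  double A = 0.0, plateau_until = -1.0, prev_qd1 = qd1, prev_q1c = 0.0;
  bool have_prev = false;

  for (int i = 0; i < n; ++i) {
    const double ti = i * dt;
    double th = 0.0;
    switch (kind) {
    case HOLD:
      th = cp["value"];
      break;
    case SINE:
      th = cp["offset"] + cp["A"] * sin(cp["w"] * ti + cp["phase"]);
      break;
    case BANGBANG: {
      if (i == 0) {
        th = cp["kick"] * cp["theta_hat"];
      } else {
        const double trq = P.k1 * (th_prev - q1);
        if (trq > cp["eps_tau"]) th = cp["theta_hat"];
        else if (trq < -cp["eps_tau"]) th = -cp["theta_hat"];
        else th = 0.0;
      }
      break;
    }
    case RANDOM: {
      if (ti >= next_reseed) {
        ramp = R::runif(cp["A_lo"], cp["A_hi"]);
        romega = R::runif(cp["w_lo"], cp["w_hi"]);
        next_reseed = ti + cp["reseed_dt"];
      }
      th = ramp * sin(romega * ti);
      break;
    }
    case PARTICIPANT: {
      const double w = cp["w"], shift = cp["shift"];
      if (i == 0) { A = cp["A0"]; }
      // amplitude regulation at pendulum turning points (qd1 sign change)
      if (have_prev && prev_qd1 * qd1 < 0.0) {
        const double px = P.l * cos(q1) + P.l * cos(q1 + q2);
        const double py = P.l * sin(q1) + P.l * sin(q1 + q2);
        const double alpha = atan2(py, px), rtip = sqrt(px * px + py * py);
        const double s = (q1 > shift) ? 1.0 : -1.0;
        const double a_t = (s > 0) ? cp["targ_left"] : cp["targ_right"];
        const double err = s * (a_t - alpha) * rtip; // >0: undershoot (m)
        if (fabs(err) > cp["deadband"]) {
          A += cp["gain"] * err;
          if (A > cp["A_max"]) A = cp["A_max"];
          if (A < cp["A_min"]) A = cp["A_min"];
        }
      }
      // optional command plateau when the link crosses q1 = 0
      if (cp["plateau"] > 0.5 && have_prev && prev_q1c * q1 < 0.0)
        plateau_until = ti + cp["plateau_dur"];
      if (ti < plateau_until) {
        th = th_prev;
      } else {
        const double psi = atan2(-qd1 / w, q1 - shift);
        th = shift + A * cos(psi + cp["phi_lag"]);
        if (cp["noise_sd"] > 0.0) th += R::rnorm(0.0, cp["noise_sd"]);
      }
      prev_qd1 = qd1; prev_q1c = q1; have_prev = true;
      break;
    }
    }
    if (!std::isfinite(th))
      stop("controller returned a non-finite command at t = %f", ti);

    t[i] = ti; theta[i] = th;
    q1v[i] = q1; q2v[i] = q2; qd1v[i] = qd1; qd2v[i] = qd2;
    tau[i] = P.k1 * (th - q1);
    th_prev = th;

    if (i < n - 1)
      for (int s = 0; s < nsub; ++s)
        rk4_step(P, h, th, q1, q2, qd1, qd2);
  }
  return List::create(_["t"] = t, _["theta"] = theta, _["q1"] = q1v,
                      _["q2"] = q2v, _["qd1"] = qd1v, _["qd2"] = qd2v,
                      _["tau"] = tau);
}

// Classic DTW: boundary-anchored, monotone, steps {(1,0),(0,1),(1,1)};
// per-cell cost is the squared difference summed over dimensions (no root).
// [[Rcpp::export]]
double dtw_core(NumericMatrix ref, NumericMatrix qry) {
  const int n = ref.nrow(), m = qry.nrow(), D = ref.ncol();
  if (qry.ncol() != D) stop("dimension mismatch");
  std::vector<double> prev(m), cur(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double c = 0.0;
      for (int d = 0; d < D; ++d) {
        const double diff = ref(i, d) - qry(j, d);
        c += diff * diff;
      }
      double best;
      if (i == 0 && j == 0) best = 0.0;
      else if (i == 0) best = cur[j - 1];
      else if (j == 0) best = prev[j];
      else best = std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
      cur[j] = c + best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
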