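// Compiled core for the thalamocortical loop model: right-hand side,
// adaptive Dormand-Prince 5(4) stepper, attractor classifier and basin mapper.
// The parameter vector is packed by the R side in the fixed order
// (tau, m1, m2, e, e0, p, a, variant_code); variant codes are
// 0 = standard, 1 = reversed_gaba, 2 = fixed_g, 3 = fixed_h.

#include <Rcpp.h>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Pars {
  double tau, m1, m2, e, e0, p, a;
  int variant;
  bool freeze_T;
};

Pars unpack(const NumericVector& pv, bool freeze_T) {
  if (pv.size() != 8) stop("internal error: parameter vector must have length 8");
  Pars P;
  P.tau = pv[0]; P.m1 = pv[1]; P.m2 = pv[2]; P.e = pv[3];
  P.e0 = pv[4];  P.p  = pv[5]; P.a  = pv[6];
  P.variant = static_cast<int>(pv[7]);
  P.freeze_T = freeze_T;
  return P;
}

// increasing Hill response; 0^p defined as 0 for p > 0
inline double hill_up(double x, double m, double e, double p) {
  if (x <= 0.0) return 0.0;
  const double xp = std::pow(x, p), ep = std::pow(e, p);
  return m * xp / (ep + xp);
}

// Hill arguments are clamped at 0 (floating-point undershoot during
// integration must not feed negative bases into non-integer powers);
// the linear decay terms use the raw state.
void rhs(const double* y, double* dy, const Pars& P) {
  const double S = y[0] > 0.0 ? y[0] : 0.0;
  const double T = y[1] > 0.0 ? y[1] : 0.0;
  const double V = y[2] > 0.0 ? y[2] : 0.0;

  const double fV  = hill_up(V, P.m1, P.e, P.p);
  const double fVS = hill_up(V + S, P.m2, P.e, P.p);

  double drive;
  if (P.variant == 1) {                       // reversed (excitatory) GABA
    drive = hill_up(S + T, P.m1, P.e, P.p);
  } else {
    const double u  = P.a * T;
    const double gv = (P.variant == 2) ? P.m1
                    : P.m1 / (1.0 + std::pow(u / P.e, P.p));
    const double hv = (P.variant == 3) ? P.e0
                    : P.e0 + hill_up(u, P.m2, P.e, P.p);
    if (S <= 0.0) {
      drive = 0.0;
    } else {
      const double Sp = std::pow(S, P.p), hp = std::pow(hv, P.p);
      drive = gv * Sp / (Sp + hp);
    }
  }

  dy[0] = (fV - y[0]) / P.tau;
  dy[1] = P.freeze_T ? 0.0 : (fVS - y[1]) / P.tau;
  dy[2] = (drive - y[2]) / P.tau;
}

// Dormand-Prince 5(4) with FSAL and standard PI-free step control.
struct Dp45 {
  Pars P;
  double rtol, atol;
  double t;
  double y[3];
  double k1[3];
  bool have_k1;
  double h;

  void init(const double* y0, double t0, const Pars& pars,
            double rtol_, double atol_) {
    P = pars; rtol = rtol_; atol = atol_;
    t = t0;
    for (int i = 0; i < 3; ++i) y[i] = y0[i];
    have_k1 = false;
    h = 0.1 * P.tau;            // mild initial guess; controller adapts fast
  }

  // advance exactly to t_target
  void advance_to(double t_target) {
    static const double
      a21 = 1.0/5,
      a31 = 3.0/40,       a32 = 9.0/40,
      a41 = 44.0/45,      a42 = -56.0/15,      a43 = 32.0/9,
      a51 = 19372.0/6561, a52 = -25360.0/2187, a53 = 64448.0/6561, a54 = -212.0/729,
      a61 = 9017.0/3168,  a62 = -355.0/33,     a63 = 46732.0/5247, a64 = 49.0/176,
      a65 = -5103.0/18656,
      b1 = 35.0/384,   b3 = 500.0/1113, b4 = 125.0/192,
      b5 = -2187.0/6784, b6 = 11.0/84,
      e1 = 35.0/384 - 5179.0/57600, e3 = 500.0/1113 - 7571.0/16695,
      e4 = 125.0/192 - 393.0/640,   e5 = -2187.0/6784 + 92097.0/339200,
      e6 = 11.0/84 - 187.0/2100,    e7 = -1.0/40;

    const double tiny = 1e-12 * (1.0 + std::fabs(t_target));
    while (t < t_target - tiny) {
      if (!have_k1) { rhs(y, k1, P); have_k1 = true; }
      bool clipped = false;
      double hs = h;
      if (t + hs > t_target) { hs = t_target - t; clipped = true; }

      double k2[3], k3[3], k4[3], k5[3], k6[3], k7[3], w[3], ynew[3];

      for (int i = 0; i < 3; ++i) w[i] = y[i] + hs*a21*k1[i];
      rhs(w, k2, P);
      for (int i = 0; i < 3; ++i) w[i] = y[i] + hs*(a31*k1[i] + a32*k2[i]);
      rhs(w, k3, P);
      for (int i = 0; i < 3; ++i) w[i] = y[i] + hs*(a41*k1[i] + a42*k2[i] + a43*k3[i]);
      rhs(w, k4, P);
      for (int i = 0; i < 3; ++i)
        w[i] = y[i] + hs*(a51*k1[i] + a52*k2[i] + a53*k3[i] + a54*k4[i]);
      rhs(w, k5, P);
      for (int i = 0; i < 3; ++i)
        w[i] = y[i] + hs*(a61*k1[i] + a62*k2[i] + a63*k3[i] + a64*k4[i] + a65*k5[i]);
      rhs(w, k6, P);
      for (int i = 0; i < 3; ++i)
        ynew[i] = y[i] + hs*(b1*k1[i] + b3*k3[i] + b4*k4[i] + b5*k5[i] + b6*k6[i]);
      rhs(ynew, k7, P);

      double err2 = 0.0;
      for (int i = 0; i < 3; ++i) {
        const double ei = hs*(e1*k1[i] + e3*k3[i] + e4*k4[i] + e5*k5[i]
                              + e6*k6[i] + e7*k7[i]);
        const double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
        err2 += (ei / sc) * (ei / sc);
      }
      const double errn = std::sqrt(err2 / 3.0);
      double fac = (errn <= 0.0) ? 5.0
                 : std::min(5.0, std::max(0.2, 0.9 * std::pow(errn, -0.2)));

      if (errn <= 1.0) {
        t += hs;
        for (int i = 0; i < 3; ++i) { y[i] = ynew[i]; k1[i] = k7[i]; }
        double hn = hs * fac;
        if (clipped) hn = std::max(hn, h);   // do not lose step size to output clipping
        h = hn;
      } else {
        h = hs * fac;
      }
      if (h < 1e-10) {
        stop("integration failure: step size collapsed at t = %f near state "
             "(S = %g, T = %g, V = %g)", t, y[0], y[1], y[2]);
      }
    }
    t = t_target;
  }
};

void rk4_step(double* y, double hs, const Pars& P) {
  double k1[3], k2[3], k3[3], k4[3], w[3];
  rhs(y, k1, P);
  for (int i = 0; i < 3; ++i) w[i] = y[i] + 0.5*hs*k1[i];
  rhs(w, k2, P);
  for (int i = 0; i < 3; ++i) w[i] = y[i] + 0.5*hs*k2[i];
  rhs(w, k3, P);
  for (int i = 0; i < 3; ++i) w[i] = y[i] + hs*k3[i];
  rhs(w, k4, P);
  for (int i = 0; i < 3; ++i)
    y[i] += hs*(k1[i] + 2.0*k2[i] + 2.0*k3[i] + k4[i]) / 6.0;
}

// shared convergence test: close to a listed stable equilibrium AND slow
int matched_equilibrium(const double* y, const NumericMatrix& eq,
                        double tol_attract, double tol_speed, const Pars& P) {
  const int k = eq.nrow();
  int match = 0;
  for (int r = 0; r < k; ++r) {
    double d = 0.0;
    for (int i = 0; i < 3; ++i)
      d = std::max(d, std::fabs(y[i] - eq(r, i)));
    if (d < tol_attract) { match = r + 1; break; }
  }
  if (match == 0) return 0;
  double dy[3];
  rhs(y, dy, P);
  double sp = 0.0;
  for (int i = 0; i < 3; ++i) sp = std::max(sp, std::fabs(dy[i]));
  return (sp < tol_speed) ? match : 0;
}

int settle_core(const double* y0, const Pars& P, const NumericMatrix& eq,
                double tol_attract, double tol_speed, double max_horizon,
                double rtol, double atol, double dt_check) {
  int m = matched_equilibrium(y0, eq, tol_attract, tol_speed, P);
  if (m > 0) return m;
  Dp45 st;
  st.init(y0, 0.0, P, rtol, atol);
  double t = 0.0;
  while (t < max_horizon) {
    t = std::min(t + dt_check, max_horizon);
    st.advance_to(t);
    m = matched_equilibrium(st.y, eq, tol_attract, tol_speed, P);
    if (m > 0) return m;
  }
  return 0;                               // unresolved within the horizon
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_rhs(NumericVector state, NumericVector pars,
                      bool freeze_T = false) {
  Pars P = unpack(pars, freeze_T);
  double y[3] = { state[0], state[1], state[2] };
  double dy[3];
  rhs(y, dy, P);
  return NumericVector::create(dy[0], dy[1], dy[2]);
}

// [[Rcpp::export]]
NumericMatrix cpp_integrate(NumericVector y0, NumericVector pars,
                            double horizon, double dt_out,
                            double rtol, double atol,
                            int method, double h_fixed,
                            bool freeze_T = false) {
  Pars P = unpack(pars, freeze_T);
  const int n_out = static_cast<int>(std::floor(horizon / dt_out + 1e-9)) + 1;
  NumericMatrix out(n_out, 4);

  if (method == 0) {                      // adaptive Dormand-Prince 5(4)
    Dp45 st;
    double y[3] = { y0[0], y0[1], y0[2] };
    st.init(y, 0.0, P, rtol, atol);
    out(0, 0) = 0.0;
    for (int i = 0; i < 3; ++i) out(0, i + 1) = y[i];
    for (int j = 1; j < n_out; ++j) {
      st.advance_to(j * dt_out);
      out(j, 0) = st.t;
      for (int i = 0; i < 3; ++i) out(j, i + 1) = st.y[i];
    }
  } else {                                // fixed-step classical RK4
    double y[3] = { y0[0], y0[1], y0[2] };
    const int nsub = std::max(1, static_cast<int>(std::ceil(dt_out / h_fixed - 1e-9)));
    const double hs = dt_out / nsub;
    out(0, 0) = 0.0;
    for (int i = 0; i < 3; ++i) out(0, i + 1) = y[i];
    for (int j = 1; j < n_out; ++j) {
      for (int s = 0; s < nsub; ++s) rk4_step(y, hs, P);
      out(j, 0) = j * dt_out;
      for (int i = 0; i < 3; ++i) out(j, i + 1) = y[i];
    }
  }
  colnames(out) = CharacterVector::create("time", "S", "T", "V");
  return out;
}

// [[Rcpp::export]]
int cpp_settle(NumericVector y0, NumericVector pars, NumericMatrix equilibria,
               double tol_attract, double tol_speed, double max_horizon,
               double rtol, double atol, double dt_check,
               bool freeze_T = false) {
  Pars P = unpack(pars, freeze_T);
  double y[3] = { y0[0], y0[1], y0[2] };
  return settle_core(y, P, equilibria, tol_attract, tol_speed,
                     max_horizon, rtol, atol, dt_check);
}

// [[Rcpp::export]]
IntegerMatrix cpp_map_basins(NumericVector s0, NumericVector v0, double T_init,
                             NumericVector pars, NumericMatrix equilibria,
                             double tol_attract, double tol_speed,
                             double max_horizon, double rtol, double atol,
                             double dt_check, bool freeze_T = false) {
  Pars P = unpack(pars, freeze_T);
  const int ns = s0.size(), nv = v0.size();
  IntegerMatrix lab(ns, nv);
  for (int i = 0; i < ns; ++i) {
    Rcpp::checkUserInterrupt();
    for (int j = 0; j < nv; ++j) {
      double y[3] = { s0[i], T_init, v0[j] };
      lab(i, j) = settle_core(y, P, equilibria, tol_attract, tol_speed,
                              max_horizon, rtol, atol, dt_check);
    }
  }
  return lab;
}
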