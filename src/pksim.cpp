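// Compiled simulation core for the gastroretentive PK model.
//
// State (amounts, mg):
//   y[0] X_GRsystem   undissolved drug held by the GR device
//   y[1] X_Gut_trans  transit compartment (delayed delivery to the gut)
//   y[2] X_Gut        absorbing gut compartment
//   y[3] X_c          central compartment
//   y[4] X_p          peripheral compartment
//   y[5] X_elim       cumulative elimination (bookkeeping, makes mass
//                     balance assertable)
//
// Parameter vector layout (fixed order, see pk_params() on the R side):
//   0 V1, 1 V2, 2 CL, 3 CLD, 4 Tlag, 5 Kdiss0, 6 Tchange50, 7 Dissmax,
//   8 Hill, 9 Ka_trans, 10 Ka, 11 Frel
//
// Routes: 0 = IR (dose -> transit), 1 = GR (dose -> GR system),
//         2 = bolus (dose -> central; validation route, bypasses absorption)

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int NSTATE = 6;

// Time-varying first-order dissolution rate constant. Gated to exactly
// zero up to Tlag; afterwards a Hill-type activation moves the rate from
// Kdiss0 towards Kdiss0 * (1 + Dissmax). Logistic form in log space keeps
// the Hill-10 power stable for extreme arguments.
static inline double kdiss_at_c(double t, const double* p) {
  if (t <= p[4]) return 0.0;
  double u = t - p[4];
  double lf = p[8] * (std::log(u) - std::log(p[6]));
  double frac = 1.0 / (1.0 + std::exp(-lf));
  double k = p[5] * (1.0 + p[7] * frac);
  return (k > 0.0) ? k : 0.0;
}

static inline void pk_rhs_c(double t, const double* y, double* dy,
                            const double* p) {
  double kd = kdiss_at_c(t, p);
  double C1 = y[3] / p[0];
  double C2 = y[4] / p[1];
  dy[0] = -kd * y[0];
  dy[1] = kd * p[11] * y[0] - p[9] * y[1];
  dy[2] = p[9] * y[1] - p[10] * y[2];
  dy[3] = p[10] * y[2] - (p[3] + p[2]) * C1 + p[3] * C2;
  dy[4] = p[3] * (C1 - C2);
  dy[5] = p[2] * C1;
}

// Dormand-Prince 5(4) adaptive step from t towards tend (tend > t).
// Advances y in place; returns the achieved time. FSAL is not exploited
// across calls because segments restart at output/breakpoints anyway.
struct DP45 {
  const double* p;
  double rtol, atol;
  long nsteps;
  long max_steps;

  DP45(const double* p_, double rtol_, double atol_, long max_steps_)
      : p(p_), rtol(rtol_), atol(atol_), nsteps(0), max_steps(max_steps_) {}

  // returns false on step-limit exhaustion or a non-finite error
  // estimate (wild parameter values); state is then undefined
  bool integrate(double& t, double tend, double* y, double& h) {
    static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
                        c5 = 8.0 / 9;
    static const double a21 = 1.0 / 5;
    static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
    static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
    static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                        a53 = 64448.0 / 6561, a54 = -212.0 / 729;
    static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                        a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                        a65 = -5103.0 / 18656;
    static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                        b5 = -2187.0 / 6784, b6 = 11.0 / 84;
    static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                        e3 = 500.0 / 1113 - 7571.0 / 16695,
                        e4 = 125.0 / 192 - 393.0 / 640,
                        e5 = -2187.0 / 6784 + 92097.0 / 339200,
                        e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;

    double k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE], k5[NSTATE],
        k6[NSTATE], k7[NSTATE], yt[NSTATE], ynew[NSTATE];

    while (t < tend) {
      if (++nsteps > max_steps) return false;
      double remaining = tend - t;
      if (remaining <= 1e-12 * std::max(1.0, std::fabs(tend))) {
        t = tend;
        break;
      }
      // a stale tiny h from a previous segment endgame must not be
      // mistaken for convergence: re-floor it against the interval
      if (h < 1e-10) h = std::min(remaining, 1e-10);
      if (h > remaining) h = remaining;

      pk_rhs_c(t, y, k1, p);
      for (int i = 0; i < NSTATE; ++i) yt[i] = y[i] + h * a21 * k1[i];
      pk_rhs_c(t + c2 * h, yt, k2, p);
      for (int i = 0; i < NSTATE; ++i)
        yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
      pk_rhs_c(t + c3 * h, yt, k3, p);
      for (int i = 0; i < NSTATE; ++i)
        yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
      pk_rhs_c(t + c4 * h, yt, k4, p);
      for (int i = 0; i < NSTATE; ++i)
        yt[i] = y[i] +
                h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
      pk_rhs_c(t + c5 * h, yt, k5, p);
      for (int i = 0; i < NSTATE; ++i)
        yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
      pk_rhs_c(t + h, yt, k6, p);
      for (int i = 0; i < NSTATE; ++i)
        ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                              b5 * k5[i] + b6 * k6[i]);
      pk_rhs_c(t + h, ynew, k7, p);

      double err = 0.0;
      for (int i = 0; i < NSTATE; ++i) {
        double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                         e6 * k6[i] + e7 * k7[i]);
        double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
        double r = ei / sc;
        err += r * r;
      }
      err = std::sqrt(err / NSTATE);
      if (!std::isfinite(err)) return false;

      if (err <= 1.0) {
        t += h;
        for (int i = 0; i < NSTATE; ++i) y[i] = ynew[i];
      }
      double fac = (err > 0.0) ? 0.9 * std::pow(err, -0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      if (fac < 0.2) fac = 0.2;
      h *= fac;
    }
    return true;
  }
};

static void init_state(double* y, int route, double dose) {
  for (int i = 0; i < NSTATE; ++i) y[i] = 0.0;
  if (route == 1) y[0] = dose;        // GR system
  else if (route == 2) y[3] = dose;   // central bolus
  else y[1] = dose;                   // IR -> transit
}

// Solve the model over a set of output times (sorted, >= 0), returning the
// full state trajectory. Integration restarts at the dissolution lag so
// the rate switch is never stepped over.
// [[Rcpp::export]]
NumericMatrix pk_ode_cpp(NumericVector params, int route, double dose,
                         NumericVector times, double rtol = 1e-8,
                         double atol = 1e-10, double max_steps = 5e6) {
  if (params.size() != 12) stop("params must have 12 elements");
  const double* p = REAL(params);
  int nt = times.size();
  NumericMatrix out(nt, NSTATE);

  double y[NSTATE];
  init_state(y, route, dose);
  double t = 0.0, h = 1e-3;
  DP45 solver(p, rtol, atol, (long)max_steps);

  // break at Tlag (dissolution switches on) for GR dosing
  double tlag = (route == 1) ? p[4] : -1.0;

  for (int j = 0; j < nt; ++j) {
    double tj = times[j];
    if (tj < t - 1e-12) stop("output times must be non-decreasing");
    bool ok = true;
    if (tlag > t && tlag < tj) {
      ok = solver.integrate(t, tlag, y, h);
      h = std::min(h, 1e-3);  // restart small: rate jumps 0 -> Kdiss0
    }
    if (ok && tj > t) ok = solver.integrate(t, tj, y, h);
    if (!ok)
      stop("integration failure near t = %g (h = %g, %ld steps); "
           "check parameter values", t, h, solver.nsteps);
    for (int i = 0; i < NSTATE; ++i) out(j, i) = y[i];
  }
  return out;
}

// Batched log-likelihood for the E-step: one row of `theta` per parameter
// draw (12 columns, layout above). Observations follow a Gaussian error
// model on the concentration scale with sd = sqrt(sigma_add^2 +
// (sigma_prop * pred)^2). Returns per-draw log-likelihood plus the
// weighted-residual sums needed for the M-step residual update.
// [[Rcpp::export]]
List pk_loglik_cpp(NumericMatrix theta, int route, double dose,
                   NumericVector times, NumericVector obs,
                   double sigma_prop, double sigma_add, double rtol = 1e-8,
                   double atol = 1e-10, double max_steps = 2e4) {
  if (theta.ncol() != 12) stop("theta must have 12 columns");
  int ndraw = theta.nrow(), nt = times.size();
  if (obs.size() != nt) stop("times and obs lengths differ");
  NumericVector ll(ndraw), rss_prop(ndraw), rss_add(ndraw);
  const double LOG2PI = std::log(2.0 * M_PI);

  std::vector<double> p(12);
  for (int d = 0; d < ndraw; ++d) {
    for (int k = 0; k < 12; ++k) p[k] = theta(d, k);
    double y[NSTATE];
    init_state(&y[0], route, dose);
    double t = 0.0, h = 1e-3;
    DP45 solver(p.data(), rtol, atol, (long)max_steps);
    double tlag = (route == 1) ? p[4] : -1.0;

    double lld = 0.0, rp = 0.0, ra = 0.0;
    bool bad = false;
    for (int j = 0; j < nt && !bad; ++j) {
      double tj = times[j];
      bool ok = true;
      if (tlag > t && tlag < tj) {
        ok = solver.integrate(t, tlag, y, h);
        h = std::min(h, 1e-3);
      }
      if (ok && tj > t) ok = solver.integrate(t, tj, y, h);
      if (!ok) { bad = true; break; }
      double f = y[3] / p[0];
      if (!std::isfinite(f)) { bad = true; break; }
      if (f < 1e-12) f = 1e-12;
      double sd = std::sqrt(sigma_add * sigma_add +
                            sigma_prop * sigma_prop * f * f);
      double z = (obs[j] - f) / sd;
      lld += -std::log(sd) - 0.5 * z * z - 0.5 * LOG2PI;
      double rpj = (obs[j] - f) / f;
      rp += rpj * rpj;
      double raj = obs[j] - f;
      ra += raj * raj;
    }
    ll[d] = bad ? R_NegInf : lld;
    rss_prop[d] = rp;
    rss_add[d] = ra;
  }
  return List::create(_["loglik"] = ll, _["rss_prop"] = rss_prop,
                      _["rss_add"] = rss_add);
}
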