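// Compiled core of the QSS TMDD model: ODE right-hand side, adaptive
// Dormand-Prince 5(4) integration with infusion on/off breakpoints, the
// per-subject log-likelihood on log-concentrations, and the Laplace
// approximation machinery (inner mode search over the random effects).
//
// Parameter vector layout (shared with R/params.R, keep in sync):
//   0 CL, 1 V1, 2 V2, 3 Q, 4 Kss, 5 kint, 6 Rtot, 7 Rtotp,
//   8 kout, 9 Smax, 10 S50, 11 gamma
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const int NPAR = 12;

struct Pars {
  double CL, V1, V2, Q, Kss, kint, Rtot, Rtotp, kout, Smax, S50, gamma;
};

static Pars unpack(const double* p) {
  Pars q;
  q.CL = p[0]; q.V1 = p[1]; q.V2 = p[2]; q.Q = p[3]; q.Kss = p[4];
  q.kint = p[5]; q.Rtot = p[6]; q.Rtotp = p[7]; q.kout = p[8];
  q.Smax = p[9]; q.S50 = p[10]; q.gamma = p[11];
  return q;
}

// dA1/dt, dA2/dt, dA3/dt; `rate` is the running infusion rate in mg/h.
// The QSS correction denominators (>= 1 for non-negative states) divide the
// whole material balance of each binding compartment; the mediator turnover
// uses kin = kout (steady-state initial condition A3(0) = 1).
static inline void rhs(const Pars& p, const double* A, double rate, double* d) {
  const double C1 = A[0] / p.V1;
  const double C2 = A[1] / p.V2;
  const double den1 = 1.0 + p.Rtot  * p.Kss / ((p.Kss + C1) * (p.Kss + C1));
  const double den2 = 1.0 + p.Rtotp * p.Kss / ((p.Kss + C2) * (p.Kss + C2));
  const double num1 = rate
    - (p.CL * A[2] / p.V1 + p.Q / p.V1) * A[0]
    + (p.Q / p.V2) * A[1]
    - p.kint * p.Rtot * A[0] / (p.Kss + C1);
  d[0] = num1 / den1;
  d[1] = ((p.Q / p.V1) * A[0] - (p.Q / p.V2) * A[1]) / den2;
  const double x = C1 > 0.0 ? C1 : 0.0;
  double stim;
  if (p.gamma == 1.0) {
    stim = p.Smax * x / (p.S50 + x);
  } else {
    const double xg = std::pow(x, p.gamma);
    stim = p.Smax * xg / (std::pow(p.S50, p.gamma) + xg);
  }
  d[2] = p.kout * (1.0 + stim) - p.kout * A[2];
}

// Piecewise-constant infusion rate from dose events at time t (right-open
// intervals so that the rate at an on/off breakpoint belongs to the segment
// that starts there).
static inline double infusion_rate(double t,
                                   const double* amt, const double* start,
                                   const double* dur, int ndose) {
  double r = 0.0;
  for (int i = 0; i < ndose; ++i) {
    if (t >= start[i] && t < start[i] + dur[i]) r += amt[i] / dur[i];
  }
  return r;
}

// Dormand-Prince 5(4) coefficients.
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
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
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

// One Dormand-Prince 5(4) step from y over h; k1 holds the RHS at y on
// entry and the RHS at ynew on exit (FSAL).  *err is the scaled error
// estimate numerator per component (may be ignored by fixed-grid callers).
static inline void dp45_step(const Pars& p, double rate, const double* y,
                             double h, double* k1, double* ynew,
                             double* eabs) {
  const int n = 3;
  double k2[3], k3[3], k4[3], k5[3], k6[3], k7[3], ytmp[3];
  for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
  rhs(p, ytmp, rate, k2);
  for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
  rhs(p, ytmp, rate, k3);
  for (int i = 0; i < n; ++i)
    ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
  rhs(p, ytmp, rate, k4);
  for (int i = 0; i < n; ++i)
    ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
  rhs(p, ytmp, rate, k5);
  for (int i = 0; i < n; ++i)
    ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
  rhs(p, ytmp, rate, k6);
  for (int i = 0; i < n; ++i)
    ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                          b5 * k5[i] + b6 * k6[i]);
  rhs(p, ynew, rate, k7);
  for (int i = 0; i < n; ++i) {
    eabs[i] = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                   e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
    k1[i] = k7[i];
  }
}

// Step-size cap of the fixed (theta-independent) likelihood grid at time t:
// fine through the infusion and the distribution phase, coarser in the
// terminal phase.  `refine` > 1 subdivides further (grid-stability checks).
static inline double fixed_hmax(double t, double refine) {
  const double h = std::min(12.0, std::max(0.25, t / 8.0));
  return h / refine;
}

// Largest locally stable explicit step at the current state: bounded by the
// fastest eigenvalue scale of the system (central elimination/exchange,
// QSS-damped peripheral exchange, mediator turnover).
static inline double stable_h(const Pars& p, const double* y) {
  const double C2 = y[1] / p.V2;
  const double den2 = 1.0 + p.Rtotp * p.Kss / ((p.Kss + C2) * (p.Kss + C2));
  double lam = (p.CL * (1.0 + p.Smax) + p.Q) / p.V1;
  lam = std::max(lam, (p.Q / p.V2) / den2);
  lam = std::max(lam, p.kout);
  return 2.6 / std::max(lam, 1e-12);
}

// Fixed-grid integration of one segment: steps are determined by the time
// points (dose boundaries, output times) and a local stability cap, not by
// error control, so the solution responds smoothly to the parameters.
static bool integrate_segment_fixed(const Pars& p, double rate,
                                    double t0, double t1, double* y,
                                    const double* out_t, int nout,
                                    double* out_y, double refine) {
  const int n = 3;
  double k1[3], ynew[3], eabs[3];
  rhs(p, y, rate, k1);
  double t = t0;
  int iout = 0;
  long nstep_total = 0;
  while (t < t1 - 1e-12 * (1.0 + std::fabs(t1))) {
    double tnext = t1;
    if (iout < nout && out_t[iout] < tnext) tnext = out_t[iout];
    if (tnext <= t + 1e-12 * (1.0 + std::fabs(t))) {
      if (iout < nout && out_t[iout] <= t + 1e-12 * (1.0 + std::fabs(t))) {
        for (int i = 0; i < n; ++i) out_y[iout * n + i] = y[i];
        ++iout;
        continue;
      }
      break;
    }
    // Walk the gap with steps bounded by the grid rule and local stability.
    while (t < tnext - 1e-12 * (1.0 + std::fabs(tnext))) {
      const double hcap = std::min(fixed_hmax(t, refine), stable_h(p, y));
      const double rem = tnext - t;
      const int k = std::max(1, (int)std::ceil(rem / hcap - 1e-9));
      const double h = rem / k;
      if (++nstep_total > 50000L) return false;
      dp45_step(p, rate, y, h, k1, ynew, eabs);
      for (int i = 0; i < n; ++i) y[i] = ynew[i];
      if (!std::isfinite(y[0]) || !std::isfinite(y[1]) ||
          !std::isfinite(y[2])) return false;
      t += h;
    }
    t = tnext;
    if (iout < nout && out_t[iout] <= t + 1e-12 * (1.0 + std::fabs(t))) {
      for (int i = 0; i < n; ++i) out_y[iout * n + i] = y[i];
      ++iout;
    }
  }
  while (iout < nout) {
    for (int i = 0; i < n; ++i) out_y[iout * n + i] = y[i];
    ++iout;
  }
  return true;
}

// Integrate one segment [t0, t1] with constant infusion rate, writing states
// at the requested output times (sorted, all inside (t0, t1]).  y is updated
// in place to the state at t1.  Returns false on step-size collapse.
static bool integrate_segment(const Pars& p, double rate,
                              double t0, double t1, double* y,
                              const double* out_t, int nout, double* out_y,
                              double rtol, double atol) {
  const int n = 3;
  double t = t0;
  double h = std::min(0.1, t1 - t0);
  int iout = 0;
  double k1[3], k2[3], k3[3], k4[3], k5[3], k6[3], k7[3], ytmp[3], ynew[3];
  rhs(p, y, rate, k1);
  int nstep = 0;
  const int max_steps = 100000;
  while (t < t1) {
    if (++nstep > max_steps) return false;
    double tnext = t1;
    if (iout < nout && out_t[iout] < tnext) tnext = out_t[iout];
    if (h > tnext - t) h = tnext - t;
    if (h < 1e-14 * (1.0 + std::fabs(t))) h = 1e-14 * (1.0 + std::fabs(t));

    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
    rhs(p, ytmp, rate, k2);
    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    rhs(p, ytmp, rate, k3);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rhs(p, ytmp, rate, k4);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    rhs(p, ytmp, rate, k5);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
    rhs(p, ytmp, rate, k6);
    for (int i = 0; i < n; ++i)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
    rhs(p, ynew, rate, k7);

    double err = 0.0;
    for (int i = 0; i < n; ++i) {
      const double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                             e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      const double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      const double r = ei / sc;
      err += r * r;
    }
    err = std::sqrt(err / n);
    if (!std::isfinite(err)) return false;

    if (err <= 1.0) {
      t += h;
      for (int i = 0; i < n; ++i) { y[i] = ynew[i]; k1[i] = k7[i]; }  // FSAL
      while (iout < nout && out_t[iout] <= t + 1e-12 * (1.0 + std::fabs(t))) {
        for (int i = 0; i < n; ++i) out_y[iout * n + i] = y[i];
        ++iout;
      }
    }
    double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
    if (h > t1 - t0) h = t1 - t0;
  }
  // Flush any output times numerically equal to t1.
  while (iout < nout) {
    for (int i = 0; i < n; ++i) out_y[iout * n + i] = y[i];
    ++iout;
  }
  return true;
}

// Solve the system from the rest state (0, 0, 1) over the given dose events,
// reporting the state at each requested time.  `times` must be sorted and
// non-negative.
static bool solve_core(const double* p, const double* amt, const double* start,
                       const double* dur, int ndose, const double* times,
                       int ntimes, double rtol, double atol, double* out,
                       double fixed_grid = 0.0) {
  Pars pp = unpack(p);
  double y[3] = {0.0, 0.0, 1.0};

  double tmax = 0.0;
  if (ntimes > 0) tmax = times[ntimes - 1];
  for (int i = 0; i < ndose; ++i) tmax = std::max(tmax, start[i] + dur[i]);

  // Segment boundaries at infusion starts/ends.
  std::vector<double> br;
  br.push_back(0.0);
  for (int i = 0; i < ndose; ++i) {
    if (start[i] > 0.0 && start[i] < tmax) br.push_back(start[i]);
    const double e = start[i] + dur[i];
    if (e > 0.0 && e < tmax) br.push_back(e);
  }
  br.push_back(tmax);
  std::sort(br.begin(), br.end());
  br.erase(std::unique(br.begin(), br.end(),
                       [](double a, double b) { return std::fabs(a - b) < 1e-12; }),
           br.end());

  int iout = 0;
  // Output times at t = 0 get the initial state.
  while (iout < ntimes && times[iout] <= 1e-12) {
    out[iout * 3 + 0] = y[0]; out[iout * 3 + 1] = y[1]; out[iout * 3 + 2] = y[2];
    ++iout;
  }
  for (size_t s = 0; s + 1 < br.size(); ++s) {
    const double t0 = br[s], t1 = br[s + 1];
    if (t1 <= t0) continue;
    const double rate = infusion_rate(0.5 * (t0 + t1), amt, start, dur, ndose);
    int j0 = iout;
    while (iout < ntimes && times[iout] <= t1 + 1e-12 * (1.0 + t1)) ++iout;
    const bool okseg = fixed_grid > 0.0
      ? integrate_segment_fixed(pp, rate, t0, t1, y, times + j0, iout - j0,
                                out + 3 * j0, fixed_grid)
      : integrate_segment(pp, rate, t0, t1, y, times + j0, iout - j0,
                          out + 3 * j0, rtol, atol);
    if (!okseg) return false;
  }
  return true;
}

// [[Rcpp::export(name = ".tmdd_rhs_cpp")]]
NumericVector tmdd_rhs_cpp(NumericVector p, NumericVector state, double rate) {
  if (p.size() != NPAR) stop("parameter vector must have length %d", NPAR);
  double d[3];
  Pars pp = unpack(REAL(p));
  rhs(pp, REAL(state), rate, d);
  return NumericVector::create(d[0], d[1], d[2]);
}

// [[Rcpp::export(name = ".tmdd_solve_cpp")]]
NumericMatrix tmdd_solve_cpp(NumericVector p, NumericVector amt,
                             NumericVector start, NumericVector dur,
                             NumericVector times, double rtol, double atol,
                             double fixed_grid = 0.0) {
  if (p.size() != NPAR) stop("parameter vector must have length %d", NPAR);
  const int nt = times.size();
  NumericMatrix out(nt, 3);
  std::vector<double> buf(3 * (size_t)nt);
  if (!solve_core(REAL(p), REAL(amt), REAL(start), REAL(dur), amt.size(),
                  REAL(times), nt, rtol, atol, buf.data(), fixed_grid)) {
    stop("ODE integration failed (step size collapse or non-finite state)");
  }
  for (int i = 0; i < nt; ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = buf[3 * (size_t)i + j];
  colnames(out) = CharacterVector::create("A1", "A2", "A3");
  return out;
}

// Observed quantity: total drug concentration in the central compartment,
// free plus target-bound under the QSS binding relation.
static inline double total_conc(const Pars& p, double A1) {
  const double C1 = A1 / p.V1;
  return C1 + p.Rtot * C1 / (p.Kss + C1);
}

struct SubjectData {
  const double* obs_t; const double* obs_logdv; int nobs;
  const double* amt; const double* start; const double* dur; int ndose;
};

// -2 log-likelihood of one subject's log-scale observations under the
// additive log-normal residual model, at a fully specified individual
// parameter vector.
static double subject_m2ll(const double* p, double sigma, const SubjectData& d,
                           double rtol, double atol, double pred_floor,
                           bool* ok, double fixed_grid = 0.0) {
  *ok = true;
  if (d.nobs == 0) return 0.0;
  std::vector<double> buf(3 * (size_t)d.nobs);
  if (!solve_core(p, d.amt, d.start, d.dur, d.ndose, d.obs_t, d.nobs,
                  rtol, atol, buf.data(), fixed_grid)) {
    *ok = false;
    return R_PosInf;
  }
  Pars pp = unpack(p);
  const double ls2 = std::log(2.0 * M_PI * sigma * sigma);
  double s = 0.0;
  for (int i = 0; i < d.nobs; ++i) {
    double pred = total_conc(pp, buf[3 * (size_t)i]);
    if (!(pred > pred_floor)) pred = pred_floor;
    const double r = d.obs_logdv[i] - std::log(pred);
    s += ls2 + r * r / (sigma * sigma);
  }
  if (!std::isfinite(s)) { *ok = false; return R_PosInf; }
  return s;
}

// [[Rcpp::export(name = ".tmdd_subject_m2ll_cpp")]]
double tmdd_subject_m2ll_cpp(NumericVector p, double sigma,
                             NumericVector obs_t, NumericVector obs_logdv,
                             NumericVector amt, NumericVector start,
                             NumericVector dur, double rtol, double atol,
                             double pred_floor, double fixed_grid = 0.0) {
  SubjectData d;
  d.obs_t = REAL(obs_t); d.obs_logdv = REAL(obs_logdv); d.nobs = obs_t.size();
  d.amt = REAL(amt); d.start = REAL(start); d.dur = REAL(dur);
  d.ndose = amt.size();
  bool ok;
  double v = subject_m2ll(REAL(p), sigma, d, rtol, atol, pred_floor, &ok,
                          fixed_grid);
  if (!ok) stop("ODE integration failed while evaluating the likelihood");
  return v;
}

// ---- small dense linear algebra for the q x q (q <= a few) inner problem ----

static bool solve_linear(std::vector<double> A, std::vector<double>& b, int n) {
  for (int k = 0; k < n; ++k) {
    int piv = k;
    for (int i = k + 1; i < n; ++i)
      if (std::fabs(A[i * n + k]) > std::fabs(A[piv * n + k])) piv = i;
    if (std::fabs(A[piv * n + k]) < 1e-300) return false;
    if (piv != k) {
      for (int j = 0; j < n; ++j) std::swap(A[k * n + j], A[piv * n + j]);
      std::swap(b[k], b[piv]);
    }
    for (int i = k + 1; i < n; ++i) {
      const double f = A[i * n + k] / A[k * n + k];
      for (int j = k; j < n; ++j) A[i * n + j] -= f * A[k * n + j];
      b[i] -= f * b[k];
    }
  }
  for (int i = n - 1; i >= 0; --i) {
    double s = b[i];
    for (int j = i + 1; j < n; ++j) s -= A[i * n + j] * b[j];
    b[i] = s / A[i * n + i];
  }
  return true;
}

// log(det(A)) for symmetric positive definite A via Cholesky; returns false
// if A is not positive definite.
static bool logdet_spd(const std::vector<double>& A, int n, double* ld) {
  std::vector<double> L(A);
  double s = 0.0;
  for (int k = 0; k < n; ++k) {
    for (int j = 0; j < k; ++j) {
      double t = L[k * n + j];
      for (int m = 0; m < j; ++m) t -= L[k * n + m] * L[j * n + m];
      L[k * n + j] = t / L[j * n + j];
    }
    double t = L[k * n + k];
    for (int m = 0; m < k; ++m) t -= L[k * n + m] * L[k * n + m];
    if (t <= 0.0) return false;
    L[k * n + k] = std::sqrt(t);
    s += std::log(L[k * n + k]);
  }
  *ld = 2.0 * s;
  return true;
}

struct InnerProblem {
  const double* p_typ;          // typical individual params (covariates applied)
  const int* eta_idx; int q;    // which params carry exp(eta)
  const double* omega_inv;      // q x q, row major
  double logdet_omega;
  double sigma;
  const SubjectData* data;
  double rtol, atol, pred_floor, fixed_grid;
  mutable int neval;
};

// Joint -2 log of (likelihood x random-effect density), the function whose
// minimiser over eta is the empirical Bayes estimate.
static double joint_m2ll(const InnerProblem& ip, const double* eta, bool* ok) {
  double p[NPAR];
  for (int i = 0; i < NPAR; ++i) p[i] = ip.p_typ[i];
  for (int k = 0; k < ip.q; ++k) {
    double e = eta[k];
    if (e > 40.0) e = 40.0; else if (e < -40.0) e = -40.0;
    p[ip.eta_idx[k]] *= std::exp(e);
  }
  ++ip.neval;
  double ind = subject_m2ll(p, ip.sigma, *ip.data, ip.rtol, ip.atol,
                            ip.pred_floor, ok, ip.fixed_grid);
  if (!*ok) return R_PosInf;
  double quad = 0.0;
  for (int i = 0; i < ip.q; ++i)
    for (int j = 0; j < ip.q; ++j)
      quad += eta[i] * ip.omega_inv[i * ip.q + j] * eta[j];
  return ind + ip.q * std::log(2.0 * M_PI) + ip.logdet_omega + quad;
}

// Log total-concentration predictions at the individual parameters implied
// by eta.
static bool eta_logpred(const InnerProblem& ip, const double* eta,
                        std::vector<double>& lp) {
  double p[NPAR];
  for (int i = 0; i < NPAR; ++i) p[i] = ip.p_typ[i];
  for (int k = 0; k < ip.q; ++k) {
    double e = eta[k];
    if (e > 40.0) e = 40.0; else if (e < -40.0) e = -40.0;
    p[ip.eta_idx[k]] *= std::exp(e);
  }
  const SubjectData& d = *ip.data;
  lp.resize(d.nobs);
  std::vector<double> buf(3 * (size_t)d.nobs);
  ++ip.neval;
  if (!solve_core(p, d.amt, d.start, d.dur, d.ndose, d.obs_t, d.nobs,
                  ip.rtol, ip.atol, buf.data(), ip.fixed_grid)) return false;
  Pars pp = unpack(p);
  for (int i = 0; i < d.nobs; ++i) {
    double pred = total_conc(pp, buf[3 * (size_t)i]);
    if (!(pred > ip.pred_floor)) pred = ip.pred_floor;
    lp[i] = std::log(pred);
  }
  return true;
}

// Value, gradient and Gauss-Newton curvature of the joint -2ll at eta, from
// central-difference Jacobians of the log-prediction (2q + 1 ODE solves).
// The Gauss-Newton form (2 J'J / sigma^2 + 2 Omega^-1) is positive definite
// by construction and shares its evaluations with the gradient.
static bool joint_vgh(const InnerProblem& ip, const double* eta,
                      double* f, std::vector<double>& g,
                      std::vector<double>& H) {
  const int q = ip.q;
  const SubjectData& d = *ip.data;
  const int m = d.nobs;
  std::vector<double> lp, lpp, lpm, r(m), J((size_t)m * q);
  if (!eta_logpred(ip, eta, lp)) return false;
  const double s2 = ip.sigma * ip.sigma;
  const double ls2 = std::log(2.0 * M_PI * s2);
  double val = 0.0;
  for (int i = 0; i < m; ++i) {
    r[i] = d.obs_logdv[i] - lp[i];
    val += ls2 + r[i] * r[i] / s2;
  }
  std::vector<double> ep(eta, eta + q);
  for (int k = 0; k < q; ++k) {
    const double h = 1e-4 * (1.0 + std::fabs(eta[k]));
    ep[k] = eta[k] + h;
    if (!eta_logpred(ip, ep.data(), lpp)) return false;
    ep[k] = eta[k] - h;
    if (!eta_logpred(ip, ep.data(), lpm)) return false;
    ep[k] = eta[k];
    for (int i = 0; i < m; ++i) J[(size_t)i * q + k] = (lpp[i] - lpm[i]) / (2.0 * h);
  }
  g.assign(q, 0.0);
  H.assign((size_t)q * q, 0.0);
  for (int k = 0; k < q; ++k) {
    for (int i = 0; i < m; ++i) g[k] += -2.0 * r[i] * J[(size_t)i * q + k] / s2;
    for (int l = 0; l < q; ++l) {
      double hkl = 0.0;
      for (int i = 0; i < m; ++i)
        hkl += 2.0 * J[(size_t)i * q + k] * J[(size_t)i * q + l] / s2;
      H[(size_t)k * q + l] += hkl;
    }
  }
  double quad = 0.0;
  for (int i = 0; i < q; ++i) {
    for (int j = 0; j < q; ++j) {
      g[i] += 2.0 * ip.omega_inv[i * q + j] * eta[j];
      H[(size_t)i * q + j] += 2.0 * ip.omega_inv[i * q + j];
      quad += eta[i] * ip.omega_inv[i * q + j] * eta[j];
    }
  }
  *f = val + q * std::log(2.0 * M_PI) + ip.logdet_omega + quad;
  return std::isfinite(*f);
}

// Nelder-Mead over eta (dimension q), used to bracket the mode before Newton
// polishing.  Returns best point in x with value *fx.
static void nelder_mead(const InnerProblem& ip, double* x, double* fx,
                        double step, int maxit, double ftol) {
  const int n = ip.q;
  const int np = n + 1;
  std::vector<double> S((size_t)np * n), f(np);
  bool ok;
  for (int j = 0; j < n; ++j) S[j] = x[j];
  f[0] = joint_m2ll(ip, &S[0], &ok);
  for (int i = 1; i < np; ++i) {
    for (int j = 0; j < n; ++j) S[(size_t)i * n + j] = x[j];
    S[(size_t)i * n + (i - 1)] += step;
    f[i] = joint_m2ll(ip, &S[(size_t)i * n], &ok);
  }
  std::vector<double> xc(n), xr(n), xe(n), xk(n);
  for (int it = 0; it < maxit; ++it) {
    int lo = 0, hi = 0, nh = 0;
    for (int i = 1; i < np; ++i) {
      if (f[i] < f[lo]) lo = i;
      if (f[i] > f[hi]) hi = i;
    }
    nh = (hi == 0) ? 1 : 0;
    for (int i = 0; i < np; ++i)
      if (i != hi && f[i] > f[nh]) nh = i;
    if (std::fabs(f[hi] - f[lo]) < ftol * (1.0 + std::fabs(f[lo]))) break;
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int i = 0; i < np; ++i) if (i != hi) s += S[(size_t)i * n + j];
      xc[j] = s / n;
    }
    for (int j = 0; j < n; ++j) xr[j] = xc[j] + (xc[j] - S[(size_t)hi * n + j]);
    double fr = joint_m2ll(ip, xr.data(), &ok);
    if (fr < f[lo]) {
      for (int j = 0; j < n; ++j) xe[j] = xc[j] + 2.0 * (xc[j] - S[(size_t)hi * n + j]);
      double fe = joint_m2ll(ip, xe.data(), &ok);
      if (fe < fr) { std::copy(xe.begin(), xe.end(), S.begin() + (size_t)hi * n); f[hi] = fe; }
      else { std::copy(xr.begin(), xr.end(), S.begin() + (size_t)hi * n); f[hi] = fr; }
    } else if (fr < f[nh]) {
      std::copy(xr.begin(), xr.end(), S.begin() + (size_t)hi * n); f[hi] = fr;
    } else {
      for (int j = 0; j < n; ++j) xk[j] = xc[j] + 0.5 * (S[(size_t)hi * n + j] - xc[j]);
      double fk = joint_m2ll(ip, xk.data(), &ok);
      if (fk < f[hi]) { std::copy(xk.begin(), xk.end(), S.begin() + (size_t)hi * n); f[hi] = fk; }
      else {
        int lo2 = lo;
        for (int i = 0; i < np; ++i) {
          if (i == lo2) continue;
          for (int j = 0; j < n; ++j)
            S[(size_t)i * n + j] = S[(size_t)lo2 * n + j] +
              0.5 * (S[(size_t)i * n + j] - S[(size_t)lo2 * n + j]);
          f[i] = joint_m2ll(ip, &S[(size_t)i * n], &ok);
        }
      }
    }
  }
  int lo = 0;
  for (int i = 1; i < np; ++i) if (f[i] < f[lo]) lo = i;
  for (int j = 0; j < n; ++j) x[j] = S[(size_t)lo * n + j];
  *fx = f[lo];
}

static void fd_gradient(const InnerProblem& ip, const double* x, double* g) {
  const int n = ip.q;
  std::vector<double> xp(x, x + n);
  bool ok;
  for (int j = 0; j < n; ++j) {
    const double h = 1e-3 * (1.0 + std::fabs(x[j]));
    xp[j] = x[j] + h; const double fp = joint_m2ll(ip, xp.data(), &ok);
    xp[j] = x[j] - h; const double fm = joint_m2ll(ip, xp.data(), &ok);
    xp[j] = x[j];
    g[j] = (fp - fm) / (2.0 * h);
  }
}

static void fd_hessian(const InnerProblem& ip, const double* x, double f0,
                       std::vector<double>& H) {
  const int n = ip.q;
  H.assign((size_t)n * n, 0.0);
  std::vector<double> xp(x, x + n), hs(n);
  bool ok;
  for (int j = 0; j < n; ++j) hs[j] = 1e-3 * (1.0 + std::fabs(x[j]));
  std::vector<double> fpl(n), fmi(n);
  for (int j = 0; j < n; ++j) {
    xp[j] = x[j] + hs[j]; fpl[j] = joint_m2ll(ip, xp.data(), &ok);
    xp[j] = x[j] - hs[j]; fmi[j] = joint_m2ll(ip, xp.data(), &ok);
    xp[j] = x[j];
    H[(size_t)j * n + j] = (fpl[j] - 2.0 * f0 + fmi[j]) / (hs[j] * hs[j]);
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      xp[i] = x[i] + hs[i]; xp[j] = x[j] + hs[j];
      const double fpp = joint_m2ll(ip, xp.data(), &ok);
      xp[j] = x[j] - hs[j];
      const double fpm = joint_m2ll(ip, xp.data(), &ok);
      xp[i] = x[i] - hs[i]; xp[j] = x[j] + hs[j];
      const double fmp = joint_m2ll(ip, xp.data(), &ok);
      xp[j] = x[j] - hs[j];
      const double fmm = joint_m2ll(ip, xp.data(), &ok);
      xp[i] = x[i]; xp[j] = x[j];
      H[(size_t)i * n + j] = H[(size_t)j * n + i] =
        (fpp - fpm - fmp + fmm) / (4.0 * hs[i] * hs[j]);
    }
  }
}

// Laplace contribution of one subject: minimise the joint -2ll over eta, then
//   -2 log L_i  =  joint(eta_hat) - q log(2*pi) + log det H - q log 2
// with H the Hessian of the joint -2ll at the mode.
struct LaplaceOut {
  double m2ll; std::vector<double> eta; std::vector<double> hess; bool conv;
};

static LaplaceOut laplace_subject(const InnerProblem& ip, const double* eta0,
                                  bool warm, bool exact_hessian) {
  const int q = ip.q;
  LaplaceOut out; out.eta.assign(eta0, eta0 + q); out.conv = true;
  bool ok;
  double f = joint_m2ll(ip, out.eta.data(), &ok);
  if (!ok) { out.m2ll = R_PosInf; out.conv = false; return out; }

  if (!warm) nelder_mead(ip, out.eta.data(), &f, 0.4, 120, 1e-7);

  // Newton iterations with Gauss-Newton curvature; each iteration costs
  // 2q + 1 ODE solves plus the line search.
  std::vector<double> g, H, step(q), xn(q);
  bool mode_H_fresh = false;
  double f_prev = R_PosInf;
  for (int it = 0; it < 10; ++it) {
    double fv;
    if (!joint_vgh(ip, out.eta.data(), &fv, g, H)) { out.conv = false; break; }
    f = fv;
    // Diminishing returns: the Laplace value only needs the mode to the
    // precision at which the objective stops moving.
    if (f_prev - f < 1e-8 * (1.0 + std::fabs(f))) { mode_H_fresh = true; break; }
    f_prev = f;
    double gn = 0.0;
    for (int j = 0; j < q; ++j) gn += g[j] * g[j];
    gn = std::sqrt(gn);
    if (gn < 1e-5) { mode_H_fresh = true; break; }
    double ridge = 0.0;
    bool have = false;
    for (int tries = 0; tries < 6 && !have; ++tries) {
      std::vector<double> A(H), b(g);
      if (ridge > 0.0)
        for (int j = 0; j < q; ++j) A[(size_t)j * q + j] += ridge;
      if (solve_linear(A, b, q)) {
        double desc = 0.0;
        for (int j = 0; j < q; ++j) desc += b[j] * g[j];
        if (desc > 0.0) { step = b; have = true; }
      }
      ridge = (ridge == 0.0) ? 1.0 : ridge * 10.0;
    }
    if (!have) { step = g; for (double& v : step) v *= 0.1; }
    double snorm = 0.0;
    for (int j = 0; j < q; ++j) snorm = std::max(snorm, std::fabs(step[j]));
    if (snorm < 1e-6) { mode_H_fresh = true; break; }
    double alpha = 1.0;
    bool improved = false;
    for (int ls = 0; ls < 6; ++ls) {
      for (int j = 0; j < q; ++j) xn[j] = out.eta[j] - alpha * step[j];
      const double fn = joint_m2ll(ip, xn.data(), &ok);
      if (ok && fn < f + 1e-12) { out.eta = xn; f = fn; improved = true; break; }
      alpha *= 0.5;
    }
    if (!improved) {
      if (warm) break;                     // already at (or very near) a mode
      nelder_mead(ip, out.eta.data(), &f, 0.05, 40, 1e-9);
      break;
    }
    double smax = 0.0;
    for (int j = 0; j < q; ++j)
      smax = std::max(smax, std::fabs(alpha * step[j]));
    if (smax < 1e-8) break;
  }

  // Curvature of the joint -2ll at the mode for the Laplace correction.
  std::vector<double> H2;
  if (exact_hessian) {
    fd_hessian(ip, out.eta.data(), f, H2);
  } else if (mode_H_fresh) {
    H2 = H;
  } else {
    double fv;
    if (joint_vgh(ip, out.eta.data(), &fv, g, H2)) f = fv;
    else { out.m2ll = R_PosInf; out.conv = false; return out; }
  }
  out.hess = H2;
  double ld;
  if (!logdet_spd(H2, q, &ld)) {
    // Non-PD curvature (flat likelihood): fall back to the prior curvature
    // 2 * Omega^{-1}, which makes the correction cancel exactly.
    std::vector<double> P((size_t)q * q);
    for (int i = 0; i < q; ++i)
      for (int j = 0; j < q; ++j) P[(size_t)i * q + j] = 2.0 * ip.omega_inv[i * q + j];
    if (!logdet_spd(P, q, &ld)) { out.m2ll = R_PosInf; out.conv = false; return out; }
    out.conv = false;
  }
  out.m2ll = f - q * std::log(2.0 * M_PI) + ld - q * std::log(2.0);
  return out;
}

// [[Rcpp::export(name = ".tmdd_marginal_cpp")]]
List tmdd_marginal_cpp(NumericMatrix pmat, double sigma, NumericMatrix omega,
                       IntegerVector eta_idx,
                       NumericVector obs_t, NumericVector obs_logdv,
                       IntegerVector obs_ptr,
                       NumericVector dose_amt, NumericVector dose_start,
                       NumericVector dose_dur, IntegerVector dose_ptr,
                       NumericMatrix eta_init, bool warm,
                       double rtol, double atol, double pred_floor,
                       double fixed_grid = 0.0, bool exact_hessian = false) {
  const int n = pmat.nrow();
  const int q = eta_idx.size();
  if (pmat.ncol() != NPAR) stop("pmat must have %d columns", NPAR);
  if (omega.nrow() != q || omega.ncol() != q) stop("omega must be %d x %d", q, q);

  // Invert omega (q x q) and get its log determinant.
  std::vector<double> om((size_t)q * q), om_inv((size_t)q * q, 0.0);
  for (int i = 0; i < q; ++i)
    for (int j = 0; j < q; ++j) om[(size_t)i * q + j] = omega(i, j);
  double logdet_om;
  if (!logdet_spd(om, q, &logdet_om))
    stop("omega matrix is not positive definite");
  for (int col = 0; col < q; ++col) {
    std::vector<double> b(q, 0.0); b[col] = 1.0;
    std::vector<double> A(om);
    if (!solve_linear(A, b, q)) stop("omega matrix is singular");
    for (int row = 0; row < q; ++row) om_inv[(size_t)row * q + col] = b[row];
  }

  NumericVector indiv(n);
  NumericMatrix eta_out(n, q);
  NumericMatrix hess_out(n, q * q);
  IntegerVector neval(n);
  LogicalVector conv(n);
  double total = 0.0;
  std::vector<double> ptyp(NPAR);
  std::vector<int> eidx(q);
  for (int k = 0; k < q; ++k) eidx[k] = eta_idx[k];

  for (int s = 0; s < n; ++s) {
    SubjectData d;
    d.obs_t = REAL(obs_t) + obs_ptr[s];
    d.obs_logdv = REAL(obs_logdv) + obs_ptr[s];
    d.nobs = obs_ptr[s + 1] - obs_ptr[s];
    d.amt = REAL(dose_amt) + dose_ptr[s];
    d.start = REAL(dose_start) + dose_ptr[s];
    d.dur = REAL(dose_dur) + dose_ptr[s];
    d.ndose = dose_ptr[s + 1] - dose_ptr[s];

    for (int i = 0; i < NPAR; ++i) ptyp[i] = pmat(s, i);
    InnerProblem ip;
    ip.p_typ = ptyp.data(); ip.eta_idx = eidx.data(); ip.q = q;
    ip.omega_inv = om_inv.data(); ip.logdet_omega = logdet_om;
    ip.sigma = sigma; ip.data = &d;
    ip.rtol = rtol; ip.atol = atol; ip.pred_floor = pred_floor;
    ip.fixed_grid = fixed_grid;
    ip.neval = 0;

    if (d.nobs == 0) {
      indiv[s] = 0.0; conv[s] = true;
      for (int k = 0; k < q; ++k) eta_out(s, k) = 0.0;
      continue;
    }
    std::vector<double> e0(q);
    for (int k = 0; k < q; ++k) e0[k] = eta_init(s, k);
    LaplaceOut lo = laplace_subject(ip, e0.data(), warm, exact_hessian);
    if (!std::isfinite(lo.m2ll))
      stop("inner optimisation failed for subject index %d", s + 1);
    indiv[s] = lo.m2ll;
    neval[s] = ip.neval;
    conv[s] = lo.conv;
    for (int k = 0; k < q; ++k) eta_out(s, k) = lo.eta[k];
    if ((int)lo.hess.size() == q * q)
      for (int k = 0; k < q * q; ++k) hess_out(s, k) = lo.hess[k];
    total += lo.m2ll;
  }
  return List::create(_["m2ll"] = total, _["indiv"] = indiv,
                      _["eta"] = eta_out, _["conv"] = conv,
                      _["hess"] = hess_out, _["neval"] = neval);
}
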