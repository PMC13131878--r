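#include <Rcpp.h>
using namespace Rcpp;

// One-compartment bolus superposition: Cp(t) = sum_{td <= t} c0_d * exp(-ke (t - td)),
// c0_d = dose / V in ng/mL. Doses are instantaneous; integration restarts at dose
// times so Cp is smooth within any RK4 step.
// n_active: number of doses already given at the start of the current
// integration span. Spans never contain a dose time in their interior, and
// a dose given exactly at a span's right endpoint must not leak into the
// stage evaluations of that span.
static inline double cp_at(double t, const NumericVector &td,
                           const NumericVector &c0, double ke, int n_active) {
  double cp = 0.0;
  for (int d = 0; d < n_active; ++d) {
    cp += c0[d] * std::exp(-ke * (t - td[d]));
  }
  return cp;
}

static inline double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// d(log TV)/dt for the natural-growth families, u = log TV.
// model: 0 simeoni, 1 exponential, 2 koch, 3 quadratic (TV = TV0 (1 + lam0 t)^2)
static inline double growth_u(double u, int model, double lam0, double lam1,
                              double psi, double sqrt_tv0) {
  switch (model) {
  case 0: { // lam0 / (1 + ((lam0/lam1) TV)^psi)^(1/psi), stable in logs
    double b = psi * (u + std::log(lam0) - std::log(lam1));
    return lam0 * std::exp(-log1pexp_(b) / psi);
  }
  case 1:
    return lam0;
  case 2: // Koch: dTV/dt = 2 lam0 lam1 TV / (lam1 + 2 lam0 TV)
    return 2.0 * lam0 * lam1 / (lam1 + 2.0 * lam0 * std::exp(u));
  case 3: // quadratic-in-time: dTV/dt = 2 lam0 sqrt(TV0 * TV)
    return 2.0 * lam0 * sqrt_tv0 * std::exp(-0.5 * u);
  }
  return NA_REAL;
}

// kill term in log space: k * Cp (linear) or k * Cp / (kc50 + Cp) (Michaelis-Menten)
static inline double kill_u(double cp, double kill, double kc50) {
  if (kill == 0.0 || cp <= 0.0) return 0.0;
  if (kc50 > 0.0) return kill * cp / (kc50 + cp);
  return kill * cp;
}

struct Rhs {
  int model;
  double lam0, lam1, psi, kill, kc50, ke, sqrt_tv0;
  const NumericVector &td, &c0;
  int n_active;
  Rhs(int model_, double lam0_, double lam1_, double psi_, double kill_,
      double kc50_, double ke_, double tv0_, const NumericVector &td_,
      const NumericVector &c0_)
      : model(model_), lam0(lam0_), lam1(lam1_), psi(psi_), kill(kill_),
        kc50(kc50_), ke(ke_), sqrt_tv0(std::sqrt(tv0_)), td(td_), c0(c0_),
        n_active(0) {}
  void activate(double t_start) {
    n_active = 0;
    while (n_active < td.size() && td[n_active] <= t_start + 1e-12) ++n_active;
  }
  double operator()(double t, double u) const {
    return growth_u(u, model, lam0, lam1, psi, sqrt_tv0) -
           kill_u(cp_at(t, td, c0, ke, n_active), kill, kc50);
  }
};

// classic RK4 from t0 to t1 with steps of at most hmax
static double rk4_span(Rhs &f, double u, double t0, double t1,
                       double hmax) {
  double span = t1 - t0;
  if (span <= 0.0) return u;
  f.activate(t0);
  int n = (int)std::ceil(span / hmax - 1e-12);
  if (n < 1) n = 1;
  double h = span / n;
  double t = t0;
  for (int i = 0; i < n; ++i) {
    double k1 = f(t, u);
    double k2 = f(t + 0.5 * h, u + 0.5 * h * k1);
    double k3 = f(t + 0.5 * h, u + 0.5 * h * k2);
    double k4 = f(t + h, u + h * k3);
    u += h / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    t += h;
  }
  return u;
}

// [[Rcpp::export]]
NumericVector sim_tv_cpp(NumericVector times, double tv0, double lam0,
                         double lam1, double kill, double psi, int model,
                         double kc50, NumericVector dose_times,
                         NumericVector dose_conc, double ke, double hmax) {
  int n = times.size();
  NumericVector out(n);
  if (n == 0) return out;
  Rhs f(model, lam0, lam1, psi, kill, kc50, ke, tv0, dose_times, dose_conc);

  // knots: output times plus dose times (Cp discontinuities) inside the span
  std::vector<double> knots(times.begin(), times.end());
  for (int d = 0; d < dose_times.size(); ++d) {
    if (dose_times[d] > times[0] && dose_times[d] < times[n - 1])
      knots.push_back(dose_times[d]);
  }
  std::sort(knots.begin(), knots.end());
  knots.erase(std::unique(knots.begin(), knots.end()), knots.end());

  double u = std::log(tv0);
  double t = times[0];
  int iout = 0;
  // record any output time equal to start
  while (iout < n && times[iout] <= t + 1e-12) out[iout++] = std::exp(u);
  for (size_t k = 0; k < knots.size(); ++k) {
    if (knots[k] <= t + 1e-12) continue;
    u = rk4_span(f, u, t, knots[k], hmax);
    t = knots[k];
    while (iout < n && std::abs(times[iout] - t) <= 1e-9) out[iout++] = std::exp(u);
  }
  return out;
}

// population version: one row per subject, shared regimen/PK, per-subject params
// [[Rcpp::export]]
NumericMatrix sim_tv_pop_cpp(NumericVector times, NumericVector tv0,
                             NumericVector lam0, NumericVector lam1,
                             NumericVector kill, double psi, int model,
                             double kc50, NumericVector dose_times,
                             NumericVector dose_conc, double ke, double hmax) {
  int ns = tv0.size(), nt = times.size();
  NumericMatrix out(ns, nt);
  for (int i = 0; i < ns; ++i) {
    NumericVector tv = sim_tv_cpp(times, tv0[i], lam0[i], lam1[i], kill[i],
                                  psi, model, kc50, dose_times, dose_conc, ke,
                                  hmax);
    for (int j = 0; j < nt; ++j) out(i, j) = tv[j];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cp_profile_cpp(NumericVector times, NumericVector dose_times,
                             NumericVector dose_conc, double ke) {
  int n = times.size();
  NumericVector out(n);
  for (int j = 0; j < n; ++j) {
    int n_act = 0;
    while (n_act < dose_times.size() && dose_times[n_act] <= times[j] + 1e-12)
      ++n_act;
    out[j] = cp_at(times[j], dose_times, dose_conc, ke, n_act);
  }
  return out;
}
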