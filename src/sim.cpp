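#include <Rcpp.h>
using namespace Rcpp;

// Family codes shared with R/models.R (see .family_code()):
// 1 basic, 2 variant_drift, 3 collapsing, 4 leak, 5 urgency,
// 6 leak_urgency, 7 attractor.

static inline double attractor_dG(double x, double b, double beta,
                                  double gamma) {
  // G(x) = b (x^2 - beta x^4 + gamma x^6)
  double x2 = x * x;
  return b * x * (2.0 - 4.0 * beta * x2 + 6.0 * gamma * x2 * x2);
}

// Euler-Maruyama simulation of n trials of one model under one schedule.
//
// pars: named list of model parameters (family-dependent subset of
//   A, c, B, sA, lambda, tau, u, b, beta, gamma, Famp, Fonset, xcommit).
// drift_mat: optional (n x K) matrix of momentary stimulus drift; when
//   non-empty it replaces the constant drift A, with column index
//   floor(t / drift_dt).  Used for stimulus-driven simulations.
// bridge: apply the Brownian-bridge continuity correction for boundary
//   crossings within a step, removing the O(sqrt(dt)) discrete-time bias.
//
// Uses R's RNG so set.seed() on the R side controls reproducibility.
// [[Rcpp::export]]
List sim_trials_cpp(int family, int n, List pars, double deadline, double dt,
                    NumericMatrix drift_mat, double drift_dt, bool bridge) {
  const double A = as<double>(pars["A"]);
  const double c = as<double>(pars["c"]);
  double B = 0.0, sA = 0.0, lambda = 1.0, tau = 1.0, u = 0.0;
  double ab = 0.0, abeta = 0.0, agamma = 0.0, Famp = 0.0, Fonset = R_PosInf,
         xcommit = 1.0;
  if (family != 7) B = as<double>(pars["B"]);
  if (family == 2) sA = as<double>(pars["sA"]);
  if (family == 3) lambda = as<double>(pars["lambda"]);
  if (family == 4 || family == 6) tau = as<double>(pars["tau"]);
  if (family == 5 || family == 6) u = as<double>(pars["u"]);
  if (family == 7) {
    ab = as<double>(pars["b"]);
    abeta = as<double>(pars["beta"]);
    agamma = as<double>(pars["gamma"]);
    u = as<double>(pars["u"]);
    Famp = as<double>(pars["Famp"]);
    Fonset = as<double>(pars["Fonset"]);
    xcommit = as<double>(pars["xcommit"]);
  }
  const bool leaky = (family == 4 || family == 6);
  const double s = leaky ? c / tau : c;     // diffusion scale of dx
  const double sqdt = std::sqrt(dt);
  const double s2dt = s * s * dt;           // bridge variance per step
  const int nsteps = (int)std::floor(deadline / dt + 1e-9);
  const bool use_stim = drift_mat.nrow() > 0;
  const int K = use_stim ? drift_mat.ncol() : 0;

  IntegerVector choice(n);  // 1 upper, -1 lower, 0 none
  NumericVector rt(n, NA_REAL);
  NumericVector x_final(n);  // decision variable at absorption or deadline

  for (int i = 0; i < n; ++i) {
    double Aeff = A;
    if (family == 2) Aeff = A + sA * norm_rand();
    double x = 0.0;
    int ch = 0;
    double t_cross = NA_REAL;
    double bnd_prev = R_PosInf;
    for (int j = 1; j <= nsteps; ++j) {
      const double t0 = (j - 1) * dt;
      const double t1 = j * dt;
      double a_t = Aeff;
      if (use_stim) {
        int k = (int)std::floor(t0 / drift_dt);
        if (k >= K) k = K - 1;
        a_t = drift_mat(i, k);
      }
      double mu;
      if (leaky) {
        mu = (a_t - x) / tau;
      } else if (family == 7) {
        double urg = u * t0 + (t0 >= Fonset ? Famp : 0.0);
        mu = -attractor_dG(x, ab, abeta, agamma) + urg * x + a_t;
      } else {
        mu = a_t;
      }
      const double x1 = x + mu * dt + s * sqdt * norm_rand();
      // Instantaneous bound at the end of the step.
      double bnd;
      switch (family) {
        case 3:  bnd = B * std::exp(-t1 / lambda); break;
        case 5:
        case 6:  bnd = (u * t1 > 0) ? B / (u * t1) : R_PosInf; break;
        case 7:  bnd = xcommit; break;
        default: bnd = B;
      }
      if (x1 >= bnd) {
        ch = 1; t_cross = t1; x = x1; break;
      } else if (x1 <= -bnd) {
        ch = -1; t_cross = t1; x = x1; break;
      }
      if (bridge && R_finite(bnd)) {
        // Brownian-bridge probability that the path crossed within the
        // step although both endpoints are interior.  The bound at each
        // endpoint is used; drift cancels for the bridge at order dt.
        double b0 = R_finite(bnd_prev) ? bnd_prev : bnd;
        double pu = 0.0, pl = 0.0;
        if (b0 > x && bnd > x1)
          pu = std::exp(-2.0 * (b0 - x) * (bnd - x1) / s2dt);
        if (-b0 < x && -bnd < x1)
          pl = std::exp(-2.0 * (x + b0) * (x1 + bnd) / s2dt);
        const double v = unif_rand();
        if (v < pu) {
          ch = 1; t_cross = t1; x = x1; break;
        } else if (v < pu + pl) {
          ch = -1; t_cross = t1; x = x1; break;
        }
      }
      x = x1;
      bnd_prev = bnd;
    }
    choice[i] = ch;
    x_final[i] = x;
    if (ch != 0) rt[i] = t_cross;
  }
  return List::create(_["choice"] = choice, _["rt"] = rt,
                      _["x_final"] = x_final);
}

// Single-trial path recorder for diagnostics (no boundary stopping):
// returns the decision-variable trajectory on the full time grid.
// [[Rcpp::export]]
NumericVector sim_path_cpp(int family, List pars, double deadline, double dt,
                           NumericVector drift_t, double drift_dt) {
  const double A = as<double>(pars["A"]);
  const double c = as<double>(pars["c"]);
  double tau = 1.0, u = 0.0, ab = 0.0, abeta = 0.0, agamma = 0.0,
         Famp = 0.0, Fonset = R_PosInf;
  if (family == 4 || family == 6) tau = as<double>(pars["tau"]);
  if (family == 7) {
    ab = as<double>(pars["b"]);
    abeta = as<double>(pars["beta"]);
    agamma = as<double>(pars["gamma"]);
    u = as<double>(pars["u"]);
    Famp = as<double>(pars["Famp"]);
    Fonset = as<double>(pars["Fonset"]);
  }
  const bool leaky = (family == 4 || family == 6);
  const double s = leaky ? c / tau : c;
  const double sqdt = std::sqrt(dt);
  const int nsteps = (int)std::floor(deadline / dt + 1e-9);
  const bool use_stim = drift_t.size() > 0;
  NumericVector path(nsteps + 1);
  double x = 0.0;
  path[0] = 0.0;
  for (int j = 1; j <= nsteps; ++j) {
    const double t0 = (j - 1) * dt;
    double a_t = A;
    if (use_stim) {
      int k = (int)std::floor(t0 / drift_dt);
      if (k >= drift_t.size()) k = drift_t.size() - 1;
      a_t = drift_t[k];
    }
    double mu;
    if (leaky) {
      mu = (a_t - x) / tau;
    } else if (family == 7) {
      double urg = u * t0 + (t0 >= Fonset ? Famp : 0.0);
      mu = -attractor_dG(x, ab, abeta, agamma) + urg * x + a_t;
    } else {
      mu = a_t;
    }
    x += mu * dt + s * sqdt * norm_rand();
    path[j] = x;
  }
  return path;
}
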