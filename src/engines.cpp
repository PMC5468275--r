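// Inner loops of the synthetic-data module: analytic model potentials,
// flat-bottom restraints, overdamped Langevin / steered-pulling integrators
// and a Metropolis random-walk Boltzmann sampler.  All randomness comes from
// the R RNG (RNGScope), so set.seed() on the R side makes every run
// bit-reproducible.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Potential family codes (kept in sync with R/potentials.R):
//   1 harmonic        params: k[1..d], center[1..d]            (d = 1 or 2)
//   2 double_well     params: height h, half-separation a      (1D)
//   3 mueller_brown   params: 24 coefficients A,a,b,c,x0,y0    (2D)
//   4 polynomial      params: c0, c1, ..., cn                  (1D)

static double pot_energy(int fam, const NumericVector& p, const double* x, int d) {
  switch (fam) {
  case 1: {
    double e = 0.0;
    for (int i = 0; i < d; ++i) {
      double dx = x[i] - p[d + i];
      e += 0.5 * p[i] * dx * dx;
    }
    return e;
  }
  case 2: {
    // U(x) = h * ((x/a)^2 - 1)^2 : minima at +-a, barrier h at 0
    double u = (x[0] / p[1]) * (x[0] / p[1]) - 1.0;
    return p[0] * u * u;
  }
  case 3: {
    double e = 0.0;
    for (int k = 0; k < 4; ++k) {
      double dx = x[0] - p[16 + k];
      double dy = x[1] - p[20 + k];
      e += p[k] * std::exp(p[4 + k] * dx * dx + p[8 + k] * dx * dy + p[12 + k] * dy * dy);
    }
    return e;
  }
  case 4: {
    double e = 0.0;
    for (int k = p.size() - 1; k >= 0; --k) e = e * x[0] + p[k];
    return e;
  }
  default:
    stop("unknown potential family code %d", fam);
  }
  return NA_REAL; // not reached
}

static void pot_grad(int fam, const NumericVector& p, const double* x, int d, double* g) {
  switch (fam) {
  case 1:
    for (int i = 0; i < d; ++i) g[i] = p[i] * (x[i] - p[d + i]);
    return;
  case 2: {
    double a2 = p[1] * p[1];
    double u = x[0] * x[0] / a2 - 1.0;
    g[0] = 4.0 * p[0] * u * x[0] / a2;
    return;
  }
  case 3: {
    g[0] = 0.0; g[1] = 0.0;
    for (int k = 0; k < 4; ++k) {
      double dx = x[0] - p[16 + k];
      double dy = x[1] - p[20 + k];
      double e = p[k] * std::exp(p[4 + k] * dx * dx + p[8 + k] * dx * dy + p[12 + k] * dy * dy);
      g[0] += e * (2.0 * p[4 + k] * dx + p[8 + k] * dy);
      g[1] += e * (p[8 + k] * dx + 2.0 * p[12 + k] * dy);
    }
    return;
  }
  case 4: {
    double e = 0.0;
    for (int k = p.size() - 1; k >= 1; --k) e = e * x[0] + k * p[k];
    g[0] = e;
    return;
  }
  default:
    stop("unknown potential family code %d", fam);
  }
}

// Flat-bottom half-harmonic walls; rows of `restr` are
// (coordinate index 1-based, lower, upper, stiffness).
static double restr_energy(const NumericMatrix& restr, const double* x) {
  double e = 0.0;
  for (int r = 0; r < restr.nrow(); ++r) {
    double v = x[(int)restr(r, 0) - 1];
    if (v < restr(r, 1)) { double ex = restr(r, 1) - v; e += 0.5 * restr(r, 3) * ex * ex; }
    else if (v > restr(r, 2)) { double ex = v - restr(r, 2); e += 0.5 * restr(r, 3) * ex * ex; }
  }
  return e;
}

static void restr_grad(const NumericMatrix& restr, const double* x, double* g) {
  for (int r = 0; r < restr.nrow(); ++r) {
    int i = (int)restr(r, 0) - 1;
    double v = x[i];
    if (v < restr(r, 1)) g[i] += restr(r, 3) * (v - restr(r, 1));
    else if (v > restr(r, 2)) g[i] += restr(r, 3) * (v - restr(r, 2));
  }
}

// [[Rcpp::export(name = ".cppEvalPotential")]]
NumericVector cpp_eval_potential(int fam, NumericVector params, NumericMatrix X) {
  int n = X.nrow(), d = X.ncol();
  NumericVector out(n);
  std::vector<double> x(d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) x[j] = X(i, j);
    out[i] = pot_energy(fam, params, x.data(), d);
  }
  return out;
}

// [[Rcpp::export(name = ".cppGradPotential")]]
NumericMatrix cpp_grad_potential(int fam, NumericVector params, NumericMatrix X) {
  int n = X.nrow(), d = X.ncol();
  NumericMatrix out(n, d);
  std::vector<double> x(d), g(d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) x[j] = X(i, j);
    pot_grad(fam, params, x.data(), d, g.data());
    for (int j = 0; j < d; ++j) out(i, j) = g[j];
  }
  return out;
}

// Overdamped Euler-Maruyama: x <- x - grad(U) * dt / gamma + sqrt(2 kB T dt / gamma) * xi.
// Records steps + 1 frames (the start at t = 0 plus one per update).
// [[Rcpp::export(name = ".cppLangevin")]]
List cpp_langevin(int fam, NumericVector params, NumericMatrix restr,
                  double kBT, double gamma, double dt, int steps,
                  NumericVector start, double guard) {
  int d = start.size();
  NumericMatrix coords(steps + 1, d);
  NumericVector times(steps + 1), energies(steps + 1);
  std::vector<double> x(d), g(d);
  for (int j = 0; j < d; ++j) x[j] = start[j];
  double noise = std::sqrt(2.0 * kBT * dt / gamma);
  for (int j = 0; j < d; ++j) coords(0, j) = x[j];
  energies[0] = pot_energy(fam, params, x.data(), d) + restr_energy(restr, x.data());
  times[0] = 0.0;
  for (int s = 1; s <= steps; ++s) {
    pot_grad(fam, params, x.data(), d, g.data());
    restr_grad(restr, x.data(), g.data());
    for (int j = 0; j < d; ++j) {
      x[j] += -g[j] * dt / gamma + noise * norm_rand();
      if (!std::isfinite(x[j]) || std::fabs(x[j]) > guard)
        stop("simulation unstable at step %d: coordinate %d exceeded guard %g", s, j + 1, guard);
    }
    for (int j = 0; j < d; ++j) coords(s, j) = x[j];
    times[s] = s * dt;
    energies[s] = pot_energy(fam, params, x.data(), d) + restr_energy(restr, x.data());
  }
  return List::create(_["times"] = times, _["coords"] = coords, _["energies"] = energies);
}

// Constant-velocity steered pulling of a 1D coordinate by a moving harmonic
// restraint.  Center schedule: hold (hold_steps), linear ramp (ramp_steps),
// hold (hold_steps).  Frames are recorded every `stride` steps (last step
// always recorded).  Times in ps.
// [[Rcpp::export(name = ".cppSmd")]]
List cpp_smd(int fam, NumericVector params, double kBT, double gamma, double dt,
             double spring, double center0, double v_ps,
             int hold_steps, int ramp_steps, int stride,
             double start, double guard) {
  int total = 2 * hold_steps + ramp_steps;
  int nrec = total / stride + ((total % stride) ? 2 : 1);
  NumericVector times(nrec), coord(nrec), center(nrec);
  double x = start, g, c = center0;
  double noise = std::sqrt(2.0 * kBT * dt / gamma);
  int r = 0;
  times[r] = 0.0; coord[r] = x; center[r] = c; ++r;
  for (int s = 1; s <= total; ++s) {
    // center at the *end* of this step
    double t = s * dt;
    double t_ramp0 = hold_steps * dt, t_ramp1 = (hold_steps + ramp_steps) * dt;
    if (t <= t_ramp0) c = center0;
    else if (t <= t_ramp1) c = center0 + v_ps * (t - t_ramp0);
    else c = center0 + v_ps * (t_ramp1 - t_ramp0);
    pot_grad(fam, params, &x, 1, &g);
    g += spring * (x - c);
    x += -g * dt / gamma + noise * norm_rand();
    if (!std::isfinite(x) || std::fabs(x) > guard)
      stop("simulation unstable at step %d: coordinate exceeded guard %g", s, guard);
    if (s % stride == 0 || s == total) {
      times[r] = t; coord[r] = x; center[r] = c; ++r;
    }
  }
  if (r < nrec) { // trim in the (total %% stride == 0) case
    times = NumericVector(times.begin(), times.begin() + r);
    coord = NumericVector(coord.begin(), coord.begin() + r);
    center = NumericVector(center.begin(), center.begin() + r);
  }
  return List::create(_["times"] = times, _["coord"] = coord, _["center"] = center);
}

// Metropolis random walk targeting exp(-U/kBT); isotropic Gaussian proposals.
// Keeps n_keep states after burn-in, thinned by `thin`.
// [[Rcpp::export(name = ".cppMetropolis")]]
List cpp_metropolis(int fam, NumericVector params, double kBT,
                    int n_keep, int thin, int burn, double step_sd,
                    NumericVector start) {
  int d = start.size();
  NumericMatrix coords(n_keep, d);
  NumericVector energies(n_keep);
  std::vector<double> x(d), xp(d);
  for (int j = 0; j < d; ++j) x[j] = start[j];
  double e = pot_energy(fam, params, x.data(), d);
  long total = (long)burn + (long)n_keep * thin;
  int kept = 0;
  for (long s = 1; s <= total; ++s) {
    for (int j = 0; j < d; ++j) xp[j] = x[j] + step_sd * norm_rand();
    double ep = pot_energy(fam, params, xp.data(), d);
    if (ep <= e || unif_rand() < std::exp(-(ep - e) / kBT)) {
      x = xp; e = ep;
    }
    if (s > burn && (s - burn) % thin == 0 && kept < n_keep) {
      for (int j = 0; j < d; ++j) coords(kept, j) = x[j];
      energies[kept] = e;
      ++kept;
    }
  }
  return List::create(_["coords"] = coords, _["energies"] = energies);
}
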