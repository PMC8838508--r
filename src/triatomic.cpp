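#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Units: Angstrom, fs, amu, kcal/mol. Forces in kcal/mol/A are converted
// to amu A/fs^2 with KCAL2AKMA. Energy convention: E = k (x - x0)^2 (no 1/2),
// matching the R-side label_forcefield.
static const double KCAL2AKMA = 4.184e-04;

struct FF {
  double re, kb, theta_e, k_theta;
};

// energy (kcal/mol) and gradient (kcal/mol/A) of the triatomic;
// x, g are length-9 arrays (atom-major: x1 y1 z1 x2 ...).
static double energy_gradient(const double *x, double *g, const FF &ff) {
  for (int i = 0; i < 9; ++i) g[i] = 0.0;
  double u[3], v[3];
  for (int a = 0; a < 3; ++a) {
    u[a] = x[a] - x[3 + a];
    v[a] = x[6 + a] - x[3 + a];
  }
  double ru = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  double rv = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  if (ru < 1e-12 || rv < 1e-12) stop("triatomic geometry error: coincident atoms");
  double uh[3], vh[3];
  for (int a = 0; a < 3; ++a) { uh[a] = u[a] / ru; vh[a] = v[a] / rv; }

  double e = ff.kb * (ru - ff.re) * (ru - ff.re) +
             ff.kb * (rv - ff.re) * (rv - ff.re);
  double db1 = 2.0 * ff.kb * (ru - ff.re);
  double db3 = 2.0 * ff.kb * (rv - ff.re);
  for (int a = 0; a < 3; ++a) {
    g[a] += db1 * uh[a];
    g[6 + a] += db3 * vh[a];
    g[3 + a] -= db1 * uh[a] + db3 * vh[a];
  }

  double cth = uh[0] * vh[0] + uh[1] * vh[1] + uh[2] * vh[2];
  if (cth > 1.0) cth = 1.0;
  if (cth < -1.0) cth = -1.0;
  double th = std::acos(cth);
  double sth = std::sqrt(std::max(0.0, 1.0 - cth * cth));
  double dth = th - ff.theta_e;
  e += ff.k_theta * dth * dth;
  double f;
  if (sth < 1e-8) {
    if (std::fabs(ff.theta_e - M_PI) < 1e-12) {
      double delta = M_PI - th;
      f = 2.0 * ff.k_theta * (1.0 + delta * delta / 6.0);
    } else {
      f = -2.0 * ff.k_theta * dth / 1e-8;
    }
  } else {
    f = -2.0 * ff.k_theta * dth / sth;
  }
  for (int a = 0; a < 3; ++a) {
    double d1 = f * (vh[a] - cth * uh[a]) / ru;
    double d3 = f * (uh[a] - cth * vh[a]) / rv;
    g[a] += d1;
    g[6 + a] += d3;
    g[3 + a] -= d1 + d3;
  }
  return e;
}

// [[Rcpp::export(name = ".triatomic_eg_cpp")]]
List triatomic_eg_cpp(NumericVector x, double re, double kb,
                      double theta_e, double k_theta) {
  FF ff{re, kb, theta_e, k_theta};
  double g[9];
  double e = energy_gradient(REAL(x), g, ff);
  NumericVector grad(9);
  for (int i = 0; i < 9; ++i) grad[i] = g[i];
  return List::create(_["energy"] = e, _["gradient"] = grad);
}

// BAOAB Langevin propagation of the triatomic label.
// x0, v0: length-9 initial state; masses length 3 (amu); dt in fs;
// gamma in 1/fs; temperature in K; charges length 3 (e).
// Saves every `save_every` steps (state after the full step).
// [[Rcpp::export(name = ".triatomic_baoab_cpp")]]
List triatomic_baoab_cpp(NumericVector x0, NumericVector v0,
                         NumericVector masses, NumericVector charges,
                         double re, double kb, double theta_e, double k_theta,
                         double dt, double gamma, double temperature,
                         int n_steps, int save_every) {
  FF ff{re, kb, theta_e, k_theta};
  const double kBT = 0.0019872041 * temperature * KCAL2AKMA; // amu A^2/fs^2
  double x[9], v[9], g[9], m[9];
  for (int i = 0; i < 9; ++i) {
    x[i] = x0[i];
    v[i] = v0[i];
    m[i] = masses[i / 3];
  }
  double c1 = std::exp(-gamma * dt);
  double sig[9];
  for (int i = 0; i < 9; ++i)
    sig[i] = (gamma > 0.0) ? std::sqrt(kBT * (1.0 - c1 * c1) / m[i]) : 0.0;

  int n_save = n_steps / save_every;
  NumericMatrix coords(n_save, 9);
  NumericMatrix dipole(n_save, 3);
  NumericVector kin(n_save), pot(n_save);

  double e = energy_gradient(x, g, ff);
  RNGScope scope;
  int isave = 0;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < 9; ++i) v[i] -= 0.5 * dt * g[i] * KCAL2AKMA / m[i];
    for (int i = 0; i < 9; ++i) x[i] += 0.5 * dt * v[i];
    if (gamma > 0.0)
      for (int i = 0; i < 9; ++i) v[i] = c1 * v[i] + sig[i] * norm_rand();
    for (int i = 0; i < 9; ++i) x[i] += 0.5 * dt * v[i];
    e = energy_gradient(x, g, ff);
    for (int i = 0; i < 9; ++i) v[i] -= 0.5 * dt * g[i] * KCAL2AKMA / m[i];

    if (step % save_every == 0) {
      double ke = 0.0;
      for (int i = 0; i < 9; ++i) ke += 0.5 * m[i] * v[i] * v[i];
      kin[isave] = ke / KCAL2AKMA;   // kcal/mol
      pot[isave] = e;
      double mu[3] = {0.0, 0.0, 0.0};
      for (int at = 0; at < 3; ++at)
        for (int a = 0; a < 3; ++a) mu[a] += charges[at] * x[3 * at + a];
      for (int a = 0; a < 3; ++a) dipole(isave, a) = mu[a];
      for (int i = 0; i < 9; ++i) coords(isave, i) = x[i];
      ++isave;
    }
  }
  return List::create(_["coords"] = coords, _["dipole"] = dipole,
                      _["kinetic"] = kin, _["potential"] = pot);
}
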