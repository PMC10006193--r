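// Homogeneous uniaxial-stress driver: loading along y, lateral stretches
// solved so that the lateral Cauchy stresses vanish. Two independent lateral
// stretches because a fiber family transverse to the load axis breaks
// axisymmetry.
// [[Rcpp::depends(RcppArmadillo)]]
#include "cdm.h"

using namespace Rcpp;

namespace {

struct LateralSolve {
  double lx, lz;
  bool ok;
};

arma::mat diagF(double lx, double ly, double lz) {
  arma::mat F(3, 3, arma::fill::zeros);
  F(0, 0) = lx; F(1, 1) = ly; F(2, 2) = lz;
  return F;
}

// Newton on (sig_xx, sig_zz) = 0 with numeric Jacobian.
LateralSolve solve_lateral(double ly, double lx0, double lz0,
                           const arma::vec& a0, const MatPars& m,
                           double tol, int maxit) {
  double lx = lx0, lz = lz0;
  for (int it = 0; it < maxit; ++it) {
    arma::mat sig = cauchy_stress_F(diagF(lx, ly, lz), a0, m);
    arma::vec r = {sig(0, 0), sig(2, 2)};
    if (arma::norm(r, "inf") < tol) return {lx, lz, true};
    double h = 1e-7;
    arma::mat sx = cauchy_stress_F(diagF(lx + h, ly, lz), a0, m);
    arma::mat sz = cauchy_stress_F(diagF(lx, ly, lz + h), a0, m);
    arma::mat Jm(2, 2);
    Jm(0, 0) = (sx(0, 0) - sig(0, 0)) / h; Jm(0, 1) = (sz(0, 0) - sig(0, 0)) / h;
    Jm(1, 0) = (sx(2, 2) - sig(2, 2)) / h; Jm(1, 1) = (sz(2, 2) - sig(2, 2)) / h;
    arma::vec d;
    bool solved = arma::solve(d, Jm, -r, arma::solve_opts::no_approx);
    if (!solved || !d.is_finite()) return {lx, lz, false};
    // guard against leaving the admissible region
    double s = 1.0;
    while ((lx + s * d(0) <= 0.05 || lz + s * d(1) <= 0.05) && s > 1e-4) s *= 0.5;
    lx += s * d(0);
    lz += s * d(1);
  }
  arma::mat sig = cauchy_stress_F(diagF(lx, ly, lz), a0, m);
  bool ok = std::max(std::abs(sig(0, 0)), std::abs(sig(2, 2))) < tol;
  return {lx, lz, ok};
}

}  // namespace

// Columns of the returned matrix:
// stretch, lam_x, lam_z, J, sig0_axial, sig_axial, nominal_axial, xi, D, conv
// [[Rcpp::export]]
arma::mat cpp_simulate_uniaxial(const arma::vec& stretch_grid,
                                const arma::vec& a0,
                                const NumericVector& pars,
                                const NumericVector& dp,
                                double tol = 1e-8, int maxit = 60,
                                double dD_step = 0.05) {
  MatPars m = mat_from_vec(pars);
  int criterion = (int)dp[0];
  double mu_min = dp[1], mu_max = dp[2], D_max = dp[3];
  int n = stretch_grid.n_elem;
  arma::mat out(n, 10, arma::fill::zeros);

  double lx = 1.0, lz = 1.0, xi_max = 0.0, D = 0.0;
  double ly_prev = 1.0;
  bool terminated = false;

  for (int i = 0; i < n; ++i) {
    double ly = stretch_grid(i);
    out(i, 0) = ly;
    if (terminated) { out(i, 9) = 0; continue; }

    // sub-step if the damage increment over the interval is too large
    int nsub = 1;
    for (int attempt = 0; attempt < 8; ++attempt) {
      double lx_t = lx, lz_t = lz, xi_t = xi_max, D_t = D;
      bool ok = true, big = false;
      for (int k = 1; k <= nsub; ++k) {
        double lyk = ly_prev + (ly - ly_prev) * k / nsub;
        LateralSolve s = solve_lateral(lyk, lx_t, lz_t, a0, m, tol, maxit);
        if (!s.ok) { ok = false; break; }
        lx_t = s.lx; lz_t = s.lz;
        double xi = damage_criterion_F(diagF(lx_t, lyk, lz_t), a0, m, criterion);
        double xin = std::max(xi_t, xi);
        double Dn = damage_cdf_c(xin, mu_min, mu_max, D_max);
        if (Dn - D_t > dD_step && nsub < 128) { big = true; break; }
        xi_t = xin; D_t = Dn;
      }
      if (!ok) { terminated = true; break; }
      if (big) { nsub *= 2; continue; }
      lx = lx_t; lz = lz_t; xi_max = xi_t; D = D_t;
      break;
    }
    if (terminated) { out(i, 9) = 0; continue; }

    arma::mat F = diagF(lx, ly, lz);
    double J = arma::det(F);
    arma::mat sig0 = cauchy_stress_F(F, a0, m);
    double sig_ax = (1.0 - D) * sig0(1, 1);
    out(i, 1) = lx;
    out(i, 2) = lz;
    out(i, 3) = J;
    out(i, 4) = sig0(1, 1);
    out(i, 5) = sig_ax;
    out(i, 6) = J * sig_ax / ly;  // first Piola-Kirchhoff axial (nominal)
    out(i, 7) = xi_max;
    out(i, 8) = D;
    out(i, 9) = 1;
    ly_prev = ly;
  }
  return out;
}
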