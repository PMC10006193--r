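#ifndef MENISCUSCDM_CDM_H
#define MENISCUSCDM_CDM_H

#include <RcppArmadillo.h>

// Elastic constants in MPa (moduli) / dimensionless; lengths in mm, forces in N.
struct MatPars {
  double C1, C2, C3, C4, C5, C6, lam_m, K;
};

inline MatPars mat_from_vec(const Rcpp::NumericVector& p) {
  MatPars m;
  m.C1 = p[0]; m.C2 = p[1]; m.C3 = p[2]; m.C4 = p[3];
  m.C5 = p[4]; m.C6 = p[5]; m.lam_m = p[6]; m.K = p[7];
  return m;
}

// Fiber response in the form lambda * dF2/dlambda: zero in compression,
// exponential toe below the transition stretch, linear above it.
inline double fiber_g(double lam, const MatPars& m) {
  if (lam <= 1.0) return 0.0;
  if (lam < m.lam_m) return m.C3 * (std::exp(m.C4 * (lam - 1.0)) - 1.0);
  return m.C5 * lam + m.C6;
}

// Fiber strain energy F2(lambda) with F2(1) = 0, integrating g(s)/s.
// Toe branch has no elementary antiderivative; composite Simpson suffices
// (integrand is smooth; lam_m - 1 is small).
inline double fiber_energy(double lam, const MatPars& m) {
  if (lam <= 1.0) return 0.0;
  double upper_exp = std::min(lam, m.lam_m);
  double e = 0.0;
  int n = 200;  // even
  double h = (upper_exp - 1.0) / n;
  if (h > 0) {
    double s = 0.0;
    for (int i = 0; i <= n; ++i) {
      double x = 1.0 + i * h;
      double f = m.C3 * (std::exp(m.C4 * (x - 1.0)) - 1.0) / x;
      double w = (i == 0 || i == n) ? 1.0 : (i % 2 ? 4.0 : 2.0);
      s += w * f;
    }
    e += s * h / 3.0;
  }
  if (lam > m.lam_m)
    e += m.C5 * (lam - m.lam_m) + m.C6 * std::log(lam / m.lam_m);
  return e;
}

inline arma::mat dev3(const arma::mat& A) {
  return A - arma::trace(A) / 3.0 * arma::eye(3, 3);
}

inline double strain_energy_F(const arma::mat& F, const arma::vec& a0,
                              const MatPars& m) {
  double J = arma::det(F);
  if (J <= 0.0) Rcpp::stop("deformation gradient has non-positive determinant");
  arma::mat Ft = std::pow(J, -1.0 / 3.0) * F;
  arma::mat Bt = Ft * Ft.t();
  double I1 = arma::trace(Bt);
  double I2 = 0.5 * (I1 * I1 - arma::trace(Bt * Bt));
  double F1 = m.C1 * (std::exp(m.C2 * (I1 - 3.0)) - 1.0)
            - 0.5 * m.C1 * m.C2 * (I2 - 3.0);
  double lam = std::sqrt(arma::as_scalar(a0.t() * (Ft.t() * Ft) * a0));
  double lnJ = std::log(J);
  return F1 + fiber_energy(lam, m) + 0.5 * m.K * lnJ * lnJ;
}

// Undamaged Cauchy stress: deviatoric push-forward of the isochoric terms
// plus the volumetric pressure K ln(J)/J.
inline arma::mat cauchy_stress_F(const arma::mat& F, const arma::vec& a0,
                                 const MatPars& m) {
  double J = arma::det(F);
  if (J <= 0.0) Rcpp::stop("deformation gradient has non-positive determinant");
  arma::mat Ft = std::pow(J, -1.0 / 3.0) * F;
  arma::mat Bt = Ft * Ft.t();
  double I1 = arma::trace(Bt);
  double W1 = m.C1 * m.C2 * std::exp(m.C2 * (I1 - 3.0));
  double W2 = -0.5 * m.C1 * m.C2;
  arma::mat sig = (2.0 / J) * dev3((W1 + I1 * W2) * Bt - W2 * (Bt * Bt));
  double lam = std::sqrt(arma::as_scalar(a0.t() * (Ft.t() * Ft) * a0));
  if (lam > 1.0) {
    arma::vec mv = (Ft * a0) / lam;  // spatial (isochoric) fiber direction
    sig += (fiber_g(lam, m) / J) * dev3(mv * mv.t());
  }
  sig += (m.K * std::log(J) / J) * arma::eye(3, 3);
  return sig;
}

inline double von_mises(const arma::mat& sig) {
  arma::mat s = dev3(sig);
  return std::sqrt(1.5 * arma::accu(s % s));
}

inline double max_normal_strain_F(const arma::mat& F) {
  arma::mat E = 0.5 * (F.t() * F - arma::eye(3, 3));
  arma::vec ev = arma::eig_sym(E);
  return ev.max();
}

// criterion: 0 = von Mises stress of the undamaged stress, 1 = max normal
// Lagrange strain.
inline double damage_criterion_F(const arma::mat& F, const arma::vec& a0,
                                 const MatPars& m, int criterion) {
  if (criterion == 0) return von_mises(cauchy_stress_F(F, a0, m));
  return max_normal_strain_F(F);
}

// Quintic smoothstep CDF scaled by D_max on the middle branch so the curve
// is continuous at mu_max.
inline double damage_cdf_c(double xi, double mu_min, double mu_max,
                           double D_max) {
  if (xi <= mu_min) return 0.0;
  if (xi >= mu_max) return D_max;
  double x = (xi - mu_min) / (mu_max - mu_min);
  return D_max * x * x * x * (6.0 * x * x - 15.0 * x + 10.0);
}

#endif
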