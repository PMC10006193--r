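// [[Rcpp::depends(RcppArmadillo)]]
#include "cdm.h"

using namespace Rcpp;

// [[Rcpp::export]]
double cpp_strain_energy(const arma::mat& F, const arma::vec& a0,
                         const NumericVector& pars) {
  return strain_energy_F(F, a0, mat_from_vec(pars));
}

// [[Rcpp::export]]
arma::mat cpp_cauchy_stress(const arma::mat& F, const arma::vec& a0,
                            const NumericVector& pars) {
  return cauchy_stress_F(F, a0, mat_from_vec(pars));
}

// [[Rcpp::export]]
double cpp_fiber_g(double lam, const NumericVector& pars) {
  return fiber_g(lam, mat_from_vec(pars));
}

// [[Rcpp::export]]
double cpp_fiber_energy(double lam, const NumericVector& pars) {
  return fiber_energy(lam, mat_from_vec(pars));
}

// [[Rcpp::export]]
double cpp_von_mises(const arma::mat& sig) { return von_mises(sig); }

// [[Rcpp::export]]
double cpp_max_normal_strain(const arma::mat& F) {
  return max_normal_strain_F(F);
}

// [[Rcpp::export]]
double cpp_damage_cdf(double xi, double mu_min, double mu_max, double D_max) {
  return damage_cdf_c(xi, mu_min, mu_max, D_max);
}
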