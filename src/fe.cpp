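// Total-Lagrangian linear-tetrahedron kernels: internal force, numeric
// element tangents (central difference), per-element field extraction.
// Damage is an element scalar frozen during equilibrium iterations.
// [[Rcpp::depends(RcppArmadillo)]]
#include "cdm.h"

using namespace Rcpp;

namespace {

// Element internal force; returns false when J <= 0 (inverted element).
bool elem_force(const arma::mat& Ge, double V0, const arma::vec& a0,
                const MatPars& m, double D, const arma::mat& Ue,
                arma::vec& fe) {
  arma::mat H = Ue * Ge;                    // (3x4)(4x3) displacement gradient
  arma::mat F = arma::eye(3, 3) + H;
  double J = arma::det(F);
  if (J <= 0.0 || !std::isfinite(J)) return false;
  arma::mat sig = (1.0 - D) * cauchy_stress_F(F, a0, m);
  arma::mat P = J * sig * arma::inv(F).t(); // first Piola-Kirchhoff
  arma::mat fm = V0 * P * Ge.t();           // 3x4 nodal forces
  fe = arma::vectorise(fm);                 // column-major: node-fastest? no: comp-fastest
  return true;
}

}  // namespace

// [[Rcpp::export]]
List cpp_fe_precompute(const arma::mat& nodes, const arma::imat& tets) {
  int ne = tets.n_rows;
  arma::cube G(4, 3, ne);
  arma::vec V0(ne);
  for (int e = 0; e < ne; ++e) {
    arma::mat X(3, 4);
    for (int a = 0; a < 4; ++a) X.col(a) = nodes.row(tets(e, a)).t();
    arma::mat Dm = X.cols(1, 3);
    Dm.each_col() -= X.col(0);
    double det = arma::det(Dm);
    V0(e) = det / 6.0;
    arma::mat Dinv = arma::inv(Dm);          // rows: grad N_2..4 (as rows)
    arma::mat Ge(4, 3);
    Ge.rows(1, 3) = Dinv;
    Ge.row(0) = -arma::sum(Dinv, 0);
    G.slice(e) = Ge;
  }
  return List::create(Named("G") = G, Named("V0") = V0);
}

// [[Rcpp::export]]
List cpp_fe_internal_force(const arma::imat& tets, const arma::cube& G,
                           const arma::vec& V0, const arma::mat& fib,
                           const NumericVector& pars, const arma::vec& u,
                           const arma::vec& D) {
  MatPars m = mat_from_vec(pars);
  int ne = tets.n_rows;
  arma::vec f(u.n_elem, arma::fill::zeros);
  bool ok = true;
  arma::vec fe(12);
  for (int e = 0; e < ne && ok; ++e) {
    arma::mat Ue(3, 4);
    for (int a = 0; a < 4; ++a) Ue.col(a) = u.subvec(3 * tets(e, a), 3 * tets(e, a) + 2);
    arma::vec a0 = fib.row(e).t();
    if (!elem_force(G.slice(e), V0(e), a0, m, D(e), Ue, fe)) { ok = false; break; }
    for (int a = 0; a < 4; ++a)
      f.subvec(3 * tets(e, a), 3 * tets(e, a) + 2) += fe.subvec(3 * a, 3 * a + 2);
  }
  return List::create(Named("f") = f, Named("ok") = ok);
}

// Sparse-triplet element tangents; indices are 1-based for Matrix::sparseMatrix.
// [[Rcpp::export]]
List cpp_fe_tangent(const arma::imat& tets, const arma::cube& G,
                    const arma::vec& V0, const arma::mat& fib,
                    const NumericVector& pars, const arma::vec& u,
                    const arma::vec& D, double h = 1e-6) {
  MatPars m = mat_from_vec(pars);
  int ne = tets.n_rows;
  arma::uvec ri(144 * (size_t)ne), ci(144 * (size_t)ne);
  arma::vec xv(144 * (size_t)ne, arma::fill::zeros);
  bool ok = true;
  arma::vec fp(12), fm_(12);
  size_t t = 0;
  for (int e = 0; e < ne && ok; ++e) {
    arma::mat Ue(3, 4);
    arma::uvec dof(12);
    for (int a = 0; a < 4; ++a) {
      Ue.col(a) = u.subvec(3 * tets(e, a), 3 * tets(e, a) + 2);
      for (int c = 0; c < 3; ++c) dof(3 * a + c) = 3 * tets(e, a) + c + 1;
    }
    arma::vec a0 = fib.row(e).t();
    arma::mat Ke(12, 12);
    for (int j = 0; j < 12; ++j) {
      arma::mat Up = Ue, Um = Ue;
      Up(j % 3, j / 3) += h;
      Um(j % 3, j / 3) -= h;
      if (!elem_force(G.slice(e), V0(e), a0, m, D(e), Up, fp) ||
          !elem_force(G.slice(e), V0(e), a0, m, D(e), Um, fm_)) { ok = false; break; }
      Ke.col(j) = (fp - fm_) / (2.0 * h);
    }
    if (!ok) break;
    for (int i = 0; i < 12; ++i)
      for (int j = 0; j < 12; ++j) {
        ri(t) = dof(i); ci(t) = dof(j); xv(t) = Ke(i, j); ++t;
      }
  }
  return List::create(Named("i") = ri, Named("j") = ci, Named("x") = xv,
                      Named("ok") = ok);
}

// Per-element fields at a displacement state. Columns:
// Exx Eyy Ezz Exy Eyz Exz  S0xx S0yy S0zz S0xy S0yz S0xz  J  xi
// [[Rcpp::export]]
arma::mat cpp_fe_fields(const arma::imat& tets, const arma::cube& G,
                        const arma::mat& fib, const NumericVector& pars,
                        const arma::vec& u, int criterion) {
  MatPars m = mat_from_vec(pars);
  int ne = tets.n_rows;
  arma::mat out(ne, 14, arma::fill::zeros);
  for (int e = 0; e < ne; ++e) {
    arma::mat Ue(3, 4);
    for (int a = 0; a < 4; ++a) Ue.col(a) = u.subvec(3 * tets(e, a), 3 * tets(e, a) + 2);
    arma::mat F = arma::eye(3, 3) + Ue * G.slice(e);
    arma::mat E = 0.5 * (F.t() * F - arma::eye(3, 3));
    arma::vec a0 = fib.row(e).t();
    arma::mat S0 = cauchy_stress_F(F, a0, m);
    out(e, 0) = E(0, 0); out(e, 1) = E(1, 1); out(e, 2) = E(2, 2);
    out(e, 3) = E(0, 1); out(e, 4) = E(1, 2); out(e, 5) = E(0, 2);
    out(e, 6) = S0(0, 0); out(e, 7) = S0(1, 1); out(e, 8) = S0(2, 2);
    out(e, 9) = S0(0, 1); out(e, 10) = S0(1, 2); out(e, 11) = S0(0, 2);
    out(e, 12) = arma::det(F);
    out(e, 13) = (criterion == 0) ? von_mises(S0) : max_normal_strain_F(F);
  }
  return out;
}

// [[Rcpp::export]]
double cpp_fe_total_energy(const arma::imat& tets, const arma::cube& G,
                           const arma::vec& V0, const arma::mat& fib,
                           const NumericVector& pars, const arma::vec& u) {
  MatPars m = mat_from_vec(pars);
  int ne = tets.n_rows;
  double W = 0.0;
  for (int e = 0; e < ne; ++e) {
    arma::mat Ue(3, 4);
    for (int a = 0; a < 4; ++a) Ue.col(a) = u.subvec(3 * tets(e, a), 3 * tets(e, a) + 2);
    arma::mat F = arma::eye(3, 3) + Ue * G.slice(e);
    W += V0(e) * strain_energy_F(F, fib.row(e).t(), m);
  }
  return W;
}
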