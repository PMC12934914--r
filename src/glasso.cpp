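#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Theta-update of the ADMM splitting for the graphical lasso:
// argmin_Theta  tr(S*Theta) - w*logdet(Theta) + (rho/2)||Theta - Z + U||_F^2
// solved in closed form through the eigendecomposition of rho*(Z - U) - S.
// The weight w generalizes to the group-weighted fused objective (w = n_g);
// for the single-group glasso w = 1.
static mat theta_update(const mat& S, const mat& Z, const mat& U,
                        const double rho, const double w) {
  vec d;
  mat Q;
  mat M = rho * (Z - U) - S;
  eig_sym(d, Q, 0.5 * (M + M.t()));
  vec dt = (d + sqrt(square(d) + 4.0 * rho * w)) / (2.0 * rho);
  return Q * diagmat(dt) * Q.t();
}

static void soft_offdiag(mat& Z, const double thr) {
  const uword p = Z.n_rows;
  for (uword j = 0; j < p; ++j)
    for (uword i = 0; i < p; ++i)
      if (i != j) {
        double v = Z(i, j);
        Z(i, j) = (v > thr) ? v - thr : ((v < -thr) ? v + thr : 0.0);
      }
}

// Single-lambda graphical lasso by ADMM; the off-diagonal of the precision
// matrix is l1-penalized, the diagonal is not. Z0/U0 allow warm starts.
// [[Rcpp::export]]
Rcpp::List glasso_admm_cpp(const arma::mat& S, const double lambda,
                           const double rho, const double tol,
                           const int max_iter,
                           const arma::mat& Z0, const arma::mat& U0) {
  const uword p = S.n_rows;
  mat Z = Z0, U = U0, Theta;
  double r = datum::inf, s = datum::inf, rho_k = rho;
  int it = 0;
  bool conv = false;
  for (it = 1; it <= max_iter; ++it) {
    Theta = theta_update(S, Z, U, rho_k, 1.0);
    mat Zold = Z;
    Z = Theta + U;
    soft_offdiag(Z, lambda / rho_k);
    U += Theta - Z;
    r = norm(Theta - Z, "fro");
    s = rho_k * norm(Z - Zold, "fro");
    double eps_pri = p * tol + tol * std::max(norm(Theta, "fro"), norm(Z, "fro"));
    double eps_dua = p * tol + tol * rho_k * norm(U, "fro");
    if (r < eps_pri && s < eps_dua) { conv = true; break; }
    // residual balancing (Boyd et al. sec. 3.4.1); the scaled dual variable
    // must be rescaled whenever rho changes
    if (it % 10 == 0) {
      if (r > 10.0 * s) { rho_k *= 2.0; U /= 2.0; }
      else if (s > 10.0 * r) { rho_k /= 2.0; U *= 2.0; }
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("precision") = Z,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("primal_residual") = r,
    Rcpp::Named("dual_residual") = s,
    Rcpp::Named("converged") = conv,
    Rcpp::Named("U") = U);
}

// Graphical-lasso path over a descending lambda grid with warm starts.
// Returns the precision matrices together with edge counts and EBIC scores
// (gamma-weighted extended BIC at sample size n), so model selection needs
// no further per-lambda work in R.
// [[Rcpp::export]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                           const double rho, const double tol,
                           const int max_iter, const double n,
                           const double gamma) {
  const uword p = S.n_rows, L = lambdas.n_elem;
  cube K(p, p, L);
  ivec iters(L), edges(L);
  uvec conv(L);
  vec ebic(L);
  ebic.fill(datum::inf);
  mat Z = diagmat(1.0 / S.diag());
  mat U(p, p, fill::zeros);
  for (uword l = 0; l < L; ++l) {
    Rcpp::List fit = glasso_admm_cpp(S, lambdas(l), rho, tol, max_iter, Z, U);
    Z = Rcpp::as<mat>(fit["precision"]);
    U = Rcpp::as<mat>(fit["U"]);
    K.slice(l) = Z;
    iters(l) = Rcpp::as<int>(fit["iterations"]);
    conv(l) = Rcpp::as<bool>(fit["converged"]) ? 1 : 0;
    int E = 0;
    for (uword j = 1; j < p; ++j)
      for (uword i = 0; i < j; ++i)
        if (Z(i, j) != 0.0) ++E;
    edges(l) = E;
    if (conv(l)) {
      double ldet;
      mat C;
      if (chol(C, symmatu(Z))) {
        ldet = 2.0 * sum(log(C.diag()));
        double loglik = (n / 2.0) * (ldet - accu(S % Z));
        ebic(l) = -2.0 * loglik + E * std::log(n) +
          4.0 * gamma * E * std::log((double) p);
      }
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("precisions") = K,
    Rcpp::Named("iterations") = iters,
    Rcpp::Named("converged") = conv,
    Rcpp::Named("n_edges") = edges,
    Rcpp::Named("ebic") = ebic);
}

// Fused-lasso proximal step for two groups, entrywise on the off-diagonal:
// argmin (rho/2)[(z1-a)^2 + (z2-b)^2] + l1(|z1|+|z2|) + l2|z1-z2|.
// Fusion first (pull the pair together by l2/rho, or average if closer than
// 2*l2/rho), then soft-threshold each by l1/rho.
static inline void fused_pair(double a, double b, const double t1,
                              const double t2, double& z1, double& z2) {
  if (std::abs(a - b) <= 2.0 * t2) {
    double m = 0.5 * (a + b);
    a = m; b = m;
  } else if (a > b) {
    a -= t2; b += t2;
  } else {
    a += t2; b -= t2;
  }
  z1 = (a > t1) ? a - t1 : ((a < -t1) ? a + t1 : 0.0);
  z2 = (b > t1) ? b - t1 : ((b < -t1) ? b + t1 : 0.0);
}

// Two-group fused graphical lasso by ADMM. Minimizes
//   sum_g n_g * (tr(S_g K_g) - logdet K_g)
//     + lambda1 * sum_g ||K_g||_1,off + lambda2 * ||K_1 - K_2||_1,off
// [[Rcpp::export]]
Rcpp::List fused_glasso_cpp(const arma::mat& S1, const arma::mat& S2,
                            const double n1, const double n2,
                            const double lambda1, const double lambda2,
                            const double rho, const double tol,
                            const int max_iter,
                            Rcpp::Nullable<Rcpp::List> warm = R_NilValue) {
  const uword p = S1.n_rows;
  mat Z1 = diagmat(1.0 / S1.diag()), Z2 = diagmat(1.0 / S2.diag());
  mat U1(p, p, fill::zeros), U2(p, p, fill::zeros);
  if (warm.isNotNull()) {
    Rcpp::List w(warm);
    Z1 = Rcpp::as<mat>(w["Z1"]); Z2 = Rcpp::as<mat>(w["Z2"]);
    U1 = Rcpp::as<mat>(w["U1"]); U2 = Rcpp::as<mat>(w["U2"]);
  }
  double r = datum::inf, s = datum::inf, rho_k = rho;
  int it = 0;
  bool conv = false;
  for (it = 1; it <= max_iter; ++it) {
    mat T1 = theta_update(n1 * S1, Z1, U1, rho_k, n1);
    mat T2 = theta_update(n2 * S2, Z2, U2, rho_k, n2);
    mat Z1old = Z1, Z2old = Z2;
    mat A1 = T1 + U1, A2 = T2 + U2;
    Z1 = A1; Z2 = A2;
    const double t1 = lambda1 / rho_k, t2 = lambda2 / rho_k;
    for (uword j = 0; j < p; ++j)
      for (uword i = 0; i < p; ++i)
        if (i != j)
          fused_pair(A1(i, j), A2(i, j), t1, t2, Z1(i, j), Z2(i, j));
    U1 += T1 - Z1;
    U2 += T2 - Z2;
    r = std::sqrt(std::pow(norm(T1 - Z1, "fro"), 2) +
                  std::pow(norm(T2 - Z2, "fro"), 2));
    s = rho_k * std::sqrt(std::pow(norm(Z1 - Z1old, "fro"), 2) +
                          std::pow(norm(Z2 - Z2old, "fro"), 2));
    double sc = std::max(std::sqrt(std::pow(norm(T1, "fro"), 2) +
                                   std::pow(norm(T2, "fro"), 2)),
                         std::sqrt(std::pow(norm(Z1, "fro"), 2) +
                                   std::pow(norm(Z2, "fro"), 2)));
    double eps_pri = 2.0 * p * tol + tol * sc;
    double eps_dua = 2.0 * p * tol +
      tol * rho_k * std::sqrt(std::pow(norm(U1, "fro"), 2) +
                              std::pow(norm(U2, "fro"), 2));
    if (r < eps_pri && s < eps_dua) { conv = true; break; }
    if (it % 10 == 0) {
      if (r > 10.0 * s) { rho_k *= 2.0; U1 /= 2.0; U2 /= 2.0; }
      else if (s > 10.0 * r) { rho_k /= 2.0; U1 *= 2.0; U2 *= 2.0; }
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("precision1") = Z1,
    Rcpp::Named("precision2") = Z2,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("primal_residual") = r,
    Rcpp::Named("dual_residual") = s,
    Rcpp::Named("converged") = conv,
    Rcpp::Named("U1") = U1,
    Rcpp::Named("U2") = U2);
}
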