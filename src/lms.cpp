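// Marginal log-likelihood kernel for the latent moderated structural
// equations step of CMS, and finite-difference derivatives.
//
// Observed vector per case: (x-indicators, composite score m, y-indicators).
// Conditional on the latent predictor value t, the model is linear-Gaussian:
//   x_j | t ~ N(lambda_x[j] t, theta_x[j])                 (independent)
//   m   | t ~ N(a t, zeta_m)
//   y   | m, t ~ N(lambda_y * (tau + b t + s (m - a t) + s a t), C3)
// with s = c + d t and C3 = zeta_y lambda_y lambda_y' + diag(theta_y)
// constant in t, so each quadrature node costs O(n) after an O(n qy^2)
// precomputation. The marginal likelihood mixes the nodes with weights
// summing to one (Gauss-Hermite against the standard normal density).
//
// Parameter layout (qx x-indicators, qy y-indicators):
//   [0 .. qx-1]        lambda_x
//   [qx .. 2qx-1]      theta_x
//   [2qx]              a
//   [2qx+1]            zeta_m
//   [2qx+2]            tau
//   [2qx+3]            b
//   [2qx+4]            c
//   [2qx+5]            d
//   [2qx+6]            zeta_y
//   [2qx+7 .. +qy-2]   lambda_y[2..qy]   (lambda_y[1] fixed to 1)
//   [.. +qy]           theta_y

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static const double LOG2PI = std::log(2.0 * M_PI);

static double loglik_impl(const vec& par, const mat& X, const vec& M,
                          const mat& Y, const vec& nodes, const vec& logw) {
  const uword qx = X.n_cols, qy = Y.n_cols, n = X.n_rows, m = nodes.n_elem;
  const vec lx = par.subvec(0, qx - 1);
  const vec tx = par.subvec(qx, 2 * qx - 1);
  const double a = par(2 * qx), zm = par(2 * qx + 1), tau = par(2 * qx + 2);
  const double b = par(2 * qx + 3), c = par(2 * qx + 4), d = par(2 * qx + 5);
  const double zy = par(2 * qx + 6);
  vec ly(qy); ly(0) = 1.0;
  for (uword j = 1; j < qy; ++j) ly(j) = par(2 * qx + 6 + j);
  const vec ty = par.subvec(2 * qx + 6 + qy, 2 * qx + 5 + 2 * qy);

  // keep variances positive; a sloped penalty drives the optimizer back
  double pen = 0.0;
  for (uword j = 0; j < qx; ++j) if (tx(j) <= 0) pen += tx(j) * tx(j) + 1.0;
  for (uword j = 0; j < qy; ++j) if (ty(j) <= 0) pen += ty(j) * ty(j) + 1.0;
  if (zm <= 0) pen += zm * zm + 1.0;
  if (zy <= 0) pen += zy * zy + 1.0;
  if (pen > 0) return -1e10 * pen;

  // x-indicator block: quadratic in the node value
  const vec lx_over_tx = lx / tx;
  const double A2 = dot(lx, lx_over_tx);
  const vec A1 = X * lx_over_tx;
  vec A0(n, fill::zeros);
  for (uword j = 0; j < qx; ++j) A0 += square(X.col(j)) / tx(j);
  double cx = 0.0;
  for (uword j = 0; j < qx; ++j) cx += std::log(tx(j));
  cx = -0.5 * (cx + qx * LOG2PI);

  // y-indicator block given (m, t): Sherman-Morrison inverse of C3
  const vec dinv = 1.0 / ty;
  const vec u = ly % dinv;                       // D^-1 lambda_y
  const double s2 = dot(ly, u);                  // lambda' D^-1 lambda
  const double denom = 1.0 + zy * s2;
  // C3^-1 = D^-1 - zy u u' / denom
  const double logdetC3 = sum(log(ty)) + std::log(denom);
  const double q2 = s2 - zy * s2 * s2 / denom;   // lambda' C3^-1 lambda
  const vec Yu = Y * u;
  vec q1 = Yu - (zy * s2 / denom) * Yu;          // lambda' C3^-1 y_i
  vec q0(n, fill::zeros);
  for (uword j = 0; j < qy; ++j) q0 += square(Y.col(j)) * dinv(j);
  q0 -= (zy / denom) * square(Yu);
  const double cy = -0.5 * (logdetC3 + qy * LOG2PI);

  const double cm = -0.5 * (std::log(zm) + LOG2PI);
  const vec M2 = square(M);

  // The node-conditional log-density is bilinear in five per-observation
  // features and five per-node coefficients (mean of the Y construct given
  // (m_i, t) is tau + b t + s m_i with s = c + d t), so the n x m log-density
  // matrix is a rank-5 product plus row/column offsets.
  mat F(n, 5);
  F.col(0) = A1;
  F.col(1) = M;
  F.col(2) = M2;
  F.col(3) = M % q1;
  F.col(4) = q1;
  const vec P = (cx + cm + cy) - 0.5 * (A0 + M2 / zm + q0);
  mat C(5, m);
  vec Q(m);
  for (uword k = 0; k < m; ++k) {
    const double t = nodes(k);
    const double s = c + d * t;
    const double g0 = tau + b * t;
    C(0, k) = t;
    C(1, k) = a * t / zm - q2 * g0 * s;
    C(2, k) = -0.5 * q2 * s * s;
    C(3, k) = s;
    C(4, k) = g0;
    Q(k) = -0.5 * t * t * (A2 + a * a / zm) - 0.5 * q2 * g0 * g0 + logw(k);
  }
  mat LP = F * C;
  LP.each_row() += Q.t();
  const vec mx = max(LP, 1);
  LP.each_col() -= mx;
  const vec ll = P + mx + log(sum(exp(LP), 1));
  return accu(ll);
}

// [[Rcpp::export]]
double lms_loglik_cpp(const arma::vec& par, const arma::mat& X,
                      const arma::vec& M, const arma::mat& Y,
                      const arma::vec& nodes, const arma::vec& logw) {
  return loglik_impl(par, X, M, Y, nodes, logw);
}

// [[Rcpp::export]]
arma::vec lms_grad_cpp(const arma::vec& par, const arma::mat& X,
                       const arma::vec& M, const arma::mat& Y,
                       const arma::vec& nodes, const arma::vec& logw,
                       const double h = 1e-6, const bool central = false) {
  const uword p = par.n_elem;
  vec g(p);
  if (central) {
    for (uword j = 0; j < p; ++j) {
      const double hj = h * std::max(1.0, std::abs(par(j)));
      vec pp = par, pm = par;
      pp(j) += hj; pm(j) -= hj;
      g(j) = (loglik_impl(pp, X, M, Y, nodes, logw) -
              loglik_impl(pm, X, M, Y, nodes, logw)) / (2.0 * hj);
    }
  } else {
    const double f0 = loglik_impl(par, X, M, Y, nodes, logw);
    for (uword j = 0; j < p; ++j) {
      const double hj = h * std::max(1.0, std::abs(par(j)));
      vec pp = par;
      pp(j) += hj;
      g(j) = (loglik_impl(pp, X, M, Y, nodes, logw) - f0) / hj;
    }
  }
  return g;
}

// [[Rcpp::export]]
arma::mat lms_hess_cpp(const arma::vec& par, const arma::mat& X,
                       const arma::vec& M, const arma::mat& Y,
                       const arma::vec& nodes, const arma::vec& logw,
                       const double h = 1e-4) {
  const uword p = par.n_elem;
  vec hs(p);
  for (uword j = 0; j < p; ++j) hs(j) = h * std::max(1.0, std::abs(par(j)));
  const double f0 = loglik_impl(par, X, M, Y, nodes, logw);
  mat H(p, p);
  vec fp(p), fm(p);
  for (uword j = 0; j < p; ++j) {
    vec pp = par, pm = par;
    pp(j) += hs(j); pm(j) -= hs(j);
    fp(j) = loglik_impl(pp, X, M, Y, nodes, logw);
    fm(j) = loglik_impl(pm, X, M, Y, nodes, logw);
    H(j, j) = (fp(j) - 2.0 * f0 + fm(j)) / (hs(j) * hs(j));
  }
  for (uword j = 0; j < p; ++j) {
    for (uword k = j + 1; k < p; ++k) {
      vec ppp = par, ppm = par, pmp = par, pmm = par;
      ppp(j) += hs(j); ppp(k) += hs(k);
      ppm(j) += hs(j); ppm(k) -= hs(k);
      pmp(j) -= hs(j); pmp(k) += hs(k);
      pmm(j) -= hs(j); pmm(k) -= hs(k);
      H(j, k) = H(k, j) =
        (loglik_impl(ppp, X, M, Y, nodes, logw) -
         loglik_impl(ppm, X, M, Y, nodes, logw) -
         loglik_impl(pmp, X, M, Y, nodes, logw) +
         loglik_impl(pmm, X, M, Y, nodes, logw)) / (4.0 * hs(j) * hs(k));
    }
  }
  return H;
}
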