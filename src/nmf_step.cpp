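// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// One fused gradient evaluation of the NB factorization log-likelihood
//   mu = diag(l) * (S.rows(batch) + W*H),  X ~ NB(mu, alpha_g)
// Returns dL/dW, dL/dH, dL/dS (per batch row), dL/dl, and optionally
// dL/dalpha (per gene) and the total log-likelihood. batch0 is 0-based.
// Gradients are with respect to the natural (positive) parameters; chain
// rules for the unconstrained parameterization are applied in R.
// [[Rcpp::export]]
List nmf_step_cpp(const arma::mat& X, const arma::mat& W, const arma::mat& H,
                  const arma::mat& S, const arma::vec& l, const arma::vec& alpha,
                  const arma::uvec& batch0, bool want_ll, bool want_alpha) {
  const arma::uword n = X.n_rows, g = X.n_cols, E = S.n_rows;
  arma::mat M = W * H;                  // biological mean
  M += S.rows(batch0);                  // + ambient background
  arma::mat G(n, g);                    // dL/dmu
  arma::vec gl(n, arma::fill::zeros);   // dL/dl
  arma::vec ga(g, arma::fill::zeros);   // dL/dalpha
  double ll = 0.0;
  for (arma::uword j = 0; j < g; ++j) {
    const double a = alpha[j];
    const double la = std::log(a);
    const double lga = want_ll ? R::lgammafn(a) : 0.0;
    const double dga = want_alpha ? R::digamma(a) : 0.0;
    double gaj = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      const double m = M(i, j);         // mean before efficiency
      const double mu = m * l[i];
      const double am = a + mu;
      const double xi = X(i, j);
      double dmu;
      if (xi > 0.0) {
        dmu = xi / mu - (xi + a) / am;
        if (want_ll) {
          const double lam = std::log(am);
          ll += R::lgammafn(xi + a) - lga - R::lgammafn(xi + 1.0) +
                a * (la - lam) + xi * (std::log(mu) - lam);
        }
        if (want_alpha)
          gaj += R::digamma(xi + a) - dga + la + 1.0 - std::log(am) -
                 (xi + a) / am;
      } else {
        dmu = -a / am;
        if (want_ll) ll += a * (la - std::log(am));
        if (want_alpha) gaj += la + 1.0 - std::log(am) - a / am;
      }
      G(i, j) = dmu * l[i];             // dL/dM entry (mu = M*l)
      gl[i] += dmu * m;                 // dL/dl accumulates over genes
    }
    ga[j] = gaj;
  }
  // G currently holds dL/dM; gradients of the components follow by linearity
  arma::mat gW = G * H.t();
  arma::mat gH = W.t() * G;
  arma::mat gS(E, g, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) gS.row(batch0[i]) += G.row(i);
  return List::create(_["gW"] = gW, _["gH"] = gH, _["gS"] = gS,
                      _["gl"] = gl, _["galpha"] = ga, _["ll"] = ll);
}
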