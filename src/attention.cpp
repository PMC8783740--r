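// Batched window attention core.  All windows of one head are processed in
// one call; cubes are [tokens, head_dim, window].  Q arrives pre-scaled by
// 1/sqrt(d); bias and mask are additive score terms in [query, key]
// orientation.  The R side owns projections, residuals and parameter
// bookkeeping; only the softmax(QK' + B + M)V kernel and its adjoint live
// here.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// [[Rcpp::export]]
List attn_core_fwd(const arma::cube& Q, const arma::cube& K,
                   const arma::cube& V, const arma::mat& B,
                   const arma::cube& M) {
  uword T2 = Q.n_rows, dh = Q.n_cols, nW = Q.n_slices;
  bool has_mask = (M.n_slices == nW && M.n_rows == T2);
  cube O(T2, dh, nW), P(T2, T2, nW);
  for (uword w = 0; w < nW; ++w) {
    mat S = Q.slice(w) * K.slice(w).t() + B;
    if (has_mask) S += M.slice(w);
    S.each_col() -= arma::max(S, 1);
    mat E = arma::exp(S);
    E.each_col() /= arma::sum(E, 1);
    P.slice(w) = E;
    O.slice(w) = E * V.slice(w);
  }
  return List::create(_["O"] = O, _["P"] = P);
}

// [[Rcpp::export]]
List attn_core_bwd(const arma::cube& dO, const arma::cube& P,
                   const arma::cube& Q, const arma::cube& K,
                   const arma::cube& V) {
  uword T2 = Q.n_rows, dh = Q.n_cols, nW = Q.n_slices;
  cube dQ(T2, dh, nW), dK(T2, dh, nW), dV(T2, dh, nW);
  mat dB(T2, T2, fill::zeros);
  for (uword w = 0; w < nW; ++w) {
    mat dP = dO.slice(w) * V.slice(w).t();
    mat tmp = P.slice(w) % dP;
    vec rs = arma::sum(tmp, 1);
    mat dS = tmp - (P.slice(w).each_col() % rs);
    dB += dS;
    dQ.slice(w) = dS * K.slice(w);
    dK.slice(w) = dS.t() * Q.slice(w);
    dV.slice(w) = P.slice(w).t() * dO.slice(w);
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV, _["dB"] = dB);
}
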