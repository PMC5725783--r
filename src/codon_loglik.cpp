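// Felsenstein pruning over the 61 sense-codon state space.
// Transition matrices are reconstructed per edge from the symmetric
// eigendecomposition of the reversible generator: P(t) = A diag(e^{ev t}) B.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// edge: E x 2 (parent, child), 1-based node indices in postorder (every
// child row precedes any row using that node as parent; root = nTip + 1).
// tipPartial: list of nTip (61 x S) matrices of state indicators.
// A_list/B_list/ev_list: one entry per distinct omega value.
// t: branch length per edge; omegaIdx: E x C, 1-based into the lists.
// Returns S x C matrix of per-pattern log site likelihoods.
// [[Rcpp::export]]
arma::mat cpp_site_loglik(const arma::imat& edge, int nTip, int nNode,
                          const List& tipPartial, const List& A_list,
                          const List& B_list, const List& ev_list,
                          const arma::vec& t, const arma::imat& omegaIdx,
                          const arma::vec& pi) {
  const int E = edge.n_rows, C = omegaIdx.n_cols;
  const int nState = pi.n_elem;
  std::vector<arma::mat> tips(nTip);
  for (int i = 0; i < nTip; ++i) tips[i] = as<arma::mat>(tipPartial[i]);
  const int S = tips[0].n_cols;
  std::vector<arma::mat> As, Bs;
  std::vector<arma::vec> evs;
  for (int k = 0; k < A_list.size(); ++k) {
    As.push_back(as<arma::mat>(A_list[k]));
    Bs.push_back(as<arma::mat>(B_list[k]));
    evs.push_back(as<arma::vec>(ev_list[k]));
  }
  arma::mat out(S, C);
  const int root = nTip + 1;
  for (int c = 0; c < C; ++c) {
    arma::cube internal(nState, S, nNode, arma::fill::ones);
    arma::vec logscale(S, arma::fill::zeros);
    int lastOi = -1;
    double lastT = -1.0;
    arma::mat P;
    for (int e = 0; e < E; ++e) {
      const int p = edge(e, 0), ch = edge(e, 1);
      const int oi = omegaIdx(e, c) - 1;
      if (oi != lastOi || t(e) != lastT) {
        P = As[oi] * arma::diagmat(arma::exp(evs[oi] * t(e))) * Bs[oi];
        P.elem(arma::find(P < 0)).zeros();
        lastOi = oi; lastT = t(e);
      }
      const arma::mat& childPart =
        (ch <= nTip) ? tips[ch - 1] : internal.slice(ch - nTip - 1);
      arma::mat M = P * childPart;  // nState x S
      arma::rowvec mx = arma::max(M, 0);
      mx.elem(arma::find(mx <= 0.0)).ones();
      M.each_row() /= mx;
      logscale += arma::log(mx.t());
      internal.slice(p - nTip - 1) %= M;
    }
    arma::vec lik = (pi.t() * internal.slice(root - nTip - 1)).t();
    out.col(c) = arma::log(lik) + logscale;
  }
  return out;
}
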