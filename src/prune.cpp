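// Felsenstein pruning over the 61-codon state space, one site class.
// Partial likelihoods propagate in the eigenbasis of the (shared or
// per-edge) generator decomposition; tip partials are indicators, so tip
// edges reduce to column selection of the transition matrix. Columns are
// rescaled at each completed node to avoid underflow, accumulating log
// scalers per site pattern.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// edge: ne x 2, postorder, 1-based node ids (tips 1..ntip, root = last parent)
// didx: 1-based index per edge into lefts/rights/values
// tipstate: ntip x S, 1-based codon states, 0 = missing
// [[Rcpp::export]]
arma::vec prune_loglik_cpp(const IntegerMatrix edge, const int ntip,
                           const int nnode, const List lefts,
                           const List rights, const List values,
                           const IntegerVector didx,
                           const NumericVector elen,
                           const IntegerMatrix tipstate,
                           const NumericVector freqs) {
  const int ne = edge.nrow();
  const int S = tipstate.ncol();
  std::vector<arma::mat> partial(ntip + nnode + 1);
  std::vector<bool> haspart(ntip + nnode + 1, false);
  arma::vec logscale(S, arma::fill::zeros);
  const double xmin = std::numeric_limits<double>::min();

  for (int e = 0; e < ne; ++e) {
    const int pa = edge(e, 0);
    const int ch = edge(e, 1);
    const int d = didx[e] - 1;
    const arma::mat& L = as<arma::mat>(lefts[d]);
    const arma::mat& R = as<arma::mat>(rights[d]);
    const arma::vec ew = arma::exp(as<arma::vec>(values[d]) * elen[e]);
    arma::mat contrib(61, S);
    if (ch <= ntip) {
      arma::mat P = L * (R.each_col() % ew); // 61 x 61 transition matrix
      P.elem(arma::find(P < 0)).zeros();
      arma::vec ones61(61, arma::fill::ones);
      arma::vec pmiss = P * ones61; // rows sum to ~1; missing tip = all ones
      for (int s = 0; s < S; ++s) {
        const int st = tipstate(ch - 1, s);
        if (st == 0) {
          contrib.col(s) = pmiss;
        } else {
          contrib.col(s) = P.col(st - 1);
        }
      }
    } else {
      arma::mat X = R * partial[ch];
      X.each_col() %= ew;
      contrib = L * X;
      contrib.elem(arma::find(contrib < 0)).zeros();
      partial[ch].reset();
    }
    if (!haspart[pa]) {
      partial[pa] = contrib;
      haspart[pa] = true;
    } else {
      partial[pa] %= contrib;
    }
    const bool parent_done = (e == ne - 1) || (edge(e + 1, 0) != pa);
    if (parent_done) {
      arma::rowvec cs = arma::sum(partial[pa], 0);
      for (int s = 0; s < S; ++s) {
        double m = cs(s);
        if (!std::isfinite(m) || m <= 0) m = xmin;
        partial[pa].col(s) /= m;
        logscale(s) += std::log(m);
      }
    }
  }
  const int root = edge(ne - 1, 0);
  const arma::vec pv = as<arma::vec>(freqs);
  arma::rowvec lik = pv.t() * partial[root];
  arma::vec out(S);
  for (int s = 0; s < S; ++s) {
    double l = lik(s);
    if (!(l > 1e-300)) l = 1e-300;
    out(s) = std::log(l) + logscale(s);
  }
  return out;
}
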