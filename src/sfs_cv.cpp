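// Cross-validated candidate scoring for sequential forward selection.
//
// For every candidate feature column, computes the mean k-fold
// cross-validated accuracy of a shrinkage LDA fitted on the already
// selected columns plus that candidate. This is the compute-bound inner
// loop of the greedy selection (about 1280 candidates per step on the full
// channel set), hence the compiled implementation; the greedy loop itself
// stays in R. The discriminant matches fit_lda(): pooled within-class
// covariance shrunk toward its own diagonal, equal priors.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::vec sfs_cv_scores(const arma::mat& X, const arma::ivec& y,
                        const arma::ivec& selected,
                        const arma::ivec& candidates,
                        const arma::ivec& fold, const int nfold,
                        const int nclass, const double lambda) {
  const uword nsel = selected.n_elem;
  const uword d = nsel + 1;
  vec out(candidates.n_elem);

  std::vector<uvec> tr(nfold), te(nfold);
  for (int f = 0; f < nfold; ++f) {
    te[f] = find(fold == f);
    tr[f] = find(fold != f);
  }

  uvec cols(d);
  for (uword j = 0; j < nsel; ++j) cols[j] = (uword)selected[j];

  for (uword ci = 0; ci < candidates.n_elem; ++ci) {
    cols[d - 1] = (uword)candidates[ci];
    const mat Xs = X.cols(cols);
    double accsum = 0.0;
    int used = 0;
    for (int f = 0; f < nfold; ++f) {
      const uvec& itr = tr[f];
      const uvec& ite = te[f];
      mat Xtr = Xs.rows(itr);
      mat M(nclass, d, fill::zeros);
      vec cnt(nclass, fill::zeros);
      for (uword i = 0; i < itr.n_elem; ++i) {
        const int k = y[itr[i]];
        M.row(k) += Xtr.row(i);
        cnt[k] += 1.0;
      }
      if (cnt.min() < 2.0) continue;  // degenerate fold
      M.each_col() /= cnt;
      for (uword i = 0; i < itr.n_elem; ++i) Xtr.row(i) -= M.row(y[itr[i]]);
      mat S = (Xtr.t() * Xtr) / double(itr.n_elem - nclass);
      mat Sig = (1.0 - lambda) * S;
      Sig.diag() = S.diag();
      mat Sinv;
      if (!inv_sympd(Sinv, Sig)) continue;  // candidate scores 0 for this fold
      const mat W = Sinv * M.t();                        // d x K
      const rowvec c0 = (-0.5 * sum(M % (M * Sinv), 1)).t();
      mat sc = Xs.rows(ite) * W;
      sc.each_row() += c0;
      uword correct = 0;
      for (uword i = 0; i < ite.n_elem; ++i)
        if ((int)sc.row(i).index_max() == y[ite[i]]) ++correct;
      accsum += double(correct) / double(ite.n_elem);
      ++used;
    }
    out[ci] = used > 0 ? accsum / double(nfold) : 0.0;
  }
  return out;
}
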