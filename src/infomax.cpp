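#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// One training pass of batch extended Infomax over sphered data.
// Z: n x N sphered data; perm: 0-based sample permutation; kurt_idx:
// 0-based column indices (one row per periodic kurtosis-sign update).
// Returns the updated rotation, switching signs, and a blow-up flag.
// [[Rcpp::export(name = ".infomax_pass")]]
List infomax_pass(const arma::mat& W0, const arma::mat& Z,
                  const arma::uvec& perm, int block, double lrate,
                  const arma::vec& signs0, const arma::umat& kurt_idx,
                  int kurt_every) {
  arma::mat W = W0;
  arma::vec signs = signs0;
  int n = W.n_rows;
  int N = Z.n_cols;
  arma::mat BI = block * arma::eye(n, n);
  bool blowup = false;
  int blk = 0, kupd = 0;
  for (int s0 = 0; s0 + block <= N; s0 += block) {
    arma::uvec idx = perm.subvec(s0, s0 + block - 1);
    arma::mat u = W * Z.cols(idx);
    arma::mat y = arma::tanh(u);
    y.each_col() %= signs;
    W += lrate * ((BI - y * u.t() - u * u.t()) * W);
    if (W.has_nan() || arma::abs(W).max() > 1e8) { blowup = true; break; }
    ++blk;
    if (blk % kurt_every == 0 && kupd < (int)kurt_idx.n_rows) {
      arma::mat act = W * Z.cols(kurt_idx.row(kupd).t());
      arma::vec m2 = arma::mean(arma::square(act), 1);
      arma::vec m4 = arma::mean(arma::square(arma::square(act)), 1);
      arma::vec k = m4 / arma::square(m2) - 3.0;
      signs = arma::sign(k);
      signs.replace(0.0, 1.0);
      ++kupd;
    }
  }
  return List::create(_["W"] = W, _["signs"] = signs, _["blowup"] = blowup);
}
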