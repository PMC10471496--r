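#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Discrete-time linear recurrent recursion r_{t+1} = W r_t + drive_t.
// The drive (shared input + private noise + photostimulation) is built in R;
// only the sequential part lives here.
// [[Rcpp::export]]
arma::mat linear_recursion(const arma::mat& W, const arma::mat& drive,
                           double diverge_bound) {
  const arma::uword N = W.n_rows, T = drive.n_cols;
  arma::mat r(N, T);
  r.col(0) = drive.col(0);
  for (arma::uword t = 1; t < T; ++t) {
    r.col(t) = W * r.col(t - 1) + drive.col(t);
    if (t % 5000 == 0 && arma::abs(r.col(t)).max() > diverge_bound)
      Rcpp::stop("rate divergence at frame %d", (int)t);
  }
  if (arma::abs(r.col(T - 1)).max() > diverge_bound)
    Rcpp::stop("rate divergence at final frame");
  return r;
}
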