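// Multistatic frequency-domain backprojection kernel.
//
// I(p) = | sum_i sum_j sum_q S_ij(f_q) exp(+i k(f_q) (|p-r_i| + |p-r_j|)) |
//
// Implemented per frequency as a quadratic form: with a_i(p) = exp(i k d_i(p))
// the channel sum equals a^T S a, evaluated for all pixels at once.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
arma::vec backproject_cpp(const arma::cx_cube& S, const arma::mat& ant,
                          const arma::mat& pix, const arma::vec& k) {
  const arma::uword na = ant.n_rows;
  const arma::uword npix = pix.n_rows;
  const arma::uword nf = k.n_elem;
  if (S.n_rows != na || S.n_cols != na || S.n_slices != nf)
    Rcpp::stop("sweep/antenna/frequency dimensions disagree");

  arma::mat D(na, npix);
  for (arma::uword i = 0; i < na; ++i) {
    for (arma::uword p = 0; p < npix; ++p) {
      double dx = pix(p, 0) - ant(i, 0);
      double dy = pix(p, 1) - ant(i, 1);
      double dz = pix(p, 2) - ant(i, 2);
      D(i, p) = std::sqrt(dx * dx + dy * dy + dz * dz);
    }
  }

  arma::cx_rowvec acc(npix, arma::fill::zeros);
  for (arma::uword q = 0; q < nf; ++q) {
    arma::mat ph = k(q) * D;
    arma::cx_mat A(arma::cos(ph), arma::sin(ph));
    arma::cx_mat B = S.slice(q) * A;
    acc += arma::sum(A % B, 0);
  }
  return arma::abs(acc).t();
}
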