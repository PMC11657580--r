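// Hot kernels of the spectral matching loops: nearest neighbours in spectral
// embeddings and the ZoomOut inner iteration. Everything is double precision;
// ties in the nearest-neighbour search resolve to the smallest index,
// matching the R reference path (max.col with ties.method = "first").
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// argmin_j || x_i - y_j || for every row x_i of X over rows y_j of Y,
// computed as argmax_j (2 x_i . y_j - |y_j|^2); 1-based indices.
static uvec nn_rows(const mat& X, const mat& Y) {
  const vec yn = sum(square(Y), 1);
  const mat S = X * Y.t();  // n_x x n_y
  const uword nx = X.n_rows, ny = Y.n_rows;
  uvec out(nx);
  for (uword i = 0; i < nx; ++i) {
    double best = -datum::inf;
    uword arg = 0;
    for (uword j = 0; j < ny; ++j) {
      const double s = 2.0 * S(i, j) - yn(j);
      if (s > best) { best = s; arg = j; }
    }
    out(i) = arg + 1;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::IntegerVector cpp_nearest_index(const arma::mat& X, const arma::mat& Y) {
  uvec idx = nn_rows(X, Y);
  return Rcpp::wrap(conv_to<std::vector<int>>::from(idx));
}

// One full ZoomOut refinement: grow the k x k map C by `steps` dimensions,
// alternating the spectral nearest-neighbour conversion (target rows of
// Phi_N against C-transformed rows of Phi_M) and the mass-weighted
// projection C = Phi_N' diag(a_N) Phi_M[vmap, ].
// [[Rcpp::export]]
arma::mat cpp_zoomout(const arma::mat& C0, const arma::mat& PhiM,
                      const arma::mat& PhiN, const arma::vec& massN,
                      const int steps) {
  mat C = C0;
  uword k = C.n_rows;
  for (int s = 0; s < steps; ++s) {
    const mat EM = PhiM.cols(0, k - 1) * C.t();
    const mat EN = PhiN.cols(0, k - 1);
    const uvec vmap = nn_rows(EN, EM) - 1;
    ++k;
    const mat PhiMk = PhiM.cols(0, k - 1);
    const mat pulled = PhiMk.rows(vmap);
    mat WN = PhiN.cols(0, k - 1);
    WN.each_col() %= massN;
    C = WN.t() * pulled;
  }
  return C;
}
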