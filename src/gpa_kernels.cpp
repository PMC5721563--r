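#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Proper (det = +1) rotation R minimising ||A R - B||_F for centred k x 3
// configurations. Improper SVD solutions are corrected by flipping the
// singular direction with the smallest singular value (last column, which
// for ties is also the highest index).
static arma::mat proper_rotation(const arma::mat& A, const arma::mat& B) {
  arma::mat M = A.t() * B;
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, M)) Rcpp::stop("SVD failed in rotation solve");
  arma::mat R = U * V.t();
  if (arma::det(R) < 0.0) {
    U.col(U.n_cols - 1) *= -1.0;
    R = U * V.t();
  }
  return R;
}

// [[Rcpp::export]]
arma::mat cpp_optimal_rotation(const arma::mat& A, const arma::mat& B) {
  return proper_rotation(A, B);
}

// Rotate every slice of A onto the reference configuration.
// [[Rcpp::export]]
arma::cube cpp_rotate_all(const arma::cube& A, const arma::mat& ref) {
  arma::cube out(A.n_rows, A.n_cols, A.n_slices);
  for (arma::uword i = 0; i < A.n_slices; ++i) {
    out.slice(i) = A.slice(i) * proper_rotation(A.slice(i), ref);
  }
  return out;
}

// One sliding pass against a reference. Curve semilandmarks move along the
// chord between their two along-curve neighbours; surface semilandmarks move
// within the best-fit plane (two leading principal directions) of their
// neighbour set. Displacements are the orthogonal projection of the residual
// (reference minus current position) onto that tangent subspace, the
// minimiser of squared distance to the reference within the subspace.
// All geometry is taken from the slice as it entered the pass, so the result
// does not depend on the order in which points are processed. Indices are
// 0-based; surf_nb is the concatenation of all neighbour lists with offsets
// surf_off (length n_surf + 1).
// [[Rcpp::export]]
List cpp_slide_all(const arma::cube& A, const arma::mat& ref,
                   const IntegerVector& curve_idx,
                   const IntegerVector& curve_prev,
                   const IntegerVector& curve_next,
                   const IntegerVector& surf_idx,
                   const IntegerVector& surf_nb,
                   const IntegerVector& surf_off) {
  arma::cube out = A;
  const int n_curve = curve_idx.size();
  const int n_surf = surf_idx.size();
  int skipped = 0;

  for (arma::uword i = 0; i < A.n_slices; ++i) {
    const arma::mat X = A.slice(i);

    for (int j = 0; j < n_curve; ++j) {
      const int idx = curve_idx[j];
      arma::rowvec tang = X.row(curve_next[j]) - X.row(curve_prev[j]);
      const double nt = arma::norm(tang, 2);
      if (nt < 1e-12) {  // degenerate tangent: do not slide this pass
        ++skipped;
        continue;
      }
      tang /= nt;
      const arma::rowvec resid = ref.row(idx) - X.row(idx);
      out.slice(i).row(idx) += arma::dot(resid, tang) * tang;
    }

    for (int j = 0; j < n_surf; ++j) {
      const int idx = surf_idx[j];
      const int from = surf_off[j], to = surf_off[j + 1];
      const int m = to - from;
      arma::mat nb(m, 3);
      for (int q = 0; q < m; ++q) nb.row(q) = X.row(surf_nb[from + q]);
      nb.each_row() -= arma::mean(nb, 0);
      arma::mat cov = nb.t() * nb;
      arma::vec eval;
      arma::mat evec;
      if (!arma::eig_sym(eval, evec, cov)) {
        ++skipped;
        continue;
      }
      const double emax = eval(2);
      if (emax < 1e-24) {  // all neighbours coincident
        ++skipped;
        continue;
      }
      const arma::rowvec resid = ref.row(idx) - X.row(idx);
      arma::rowvec disp(3, arma::fill::zeros);
      // two leading principal directions span the tangent plane
      for (int d = 2; d >= 1; --d) {
        if (eval(d) < 1e-12 * emax) continue;
        const arma::rowvec e = evec.col(d).t();
        disp += arma::dot(resid, e) * e;
      }
      out.slice(i).row(idx) += disp;
    }
  }
  return List::create(_["coords"] = out, _["skipped"] = skipped);
}
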