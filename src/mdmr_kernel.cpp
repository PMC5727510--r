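// Batched per-voxel MDMR kernel.
//
// For each target voxel in a batch: assemble the subjects' connectivity
// profiles (self entry excluded), row-standardize, form the profile
// correlation matrix R across subjects, Gower-center it (G = C R C, which
// equals the Gower centering of d = sqrt(2 (1 - r))), and evaluate the
// pseudo-F for the observed and every permuted interest direction from
// trace identities:
//   numerator   q' G q
//   denominator (tr G - tr(H0 G) - q' G q) / (n - p)
// with q the unit-norm nuisance-residualized interest vectors (columns of
// qmat, observed first) and H0 = qz qz'.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// prof: list of V x nb matrices (one per subject), column k holding the
//       batch voxel k's whole-brain profile, contiguous in memory
// vox0: 0-based mask ordinals of the batch voxels (self-exclusion index)
// qz:   n x p0 orthonormal basis of the reduced design
// qmat: n x (n_perm + 1) unit residual interest directions
// [[Rcpp::export(name = ".mdmr_batch_cpp")]]
Rcpp::List mdmr_batch(const Rcpp::List& prof, const arma::ivec& vox0,
                      const arma::mat& qz, const arma::mat& qmat,
                      const int n_minus_p) {
  const uword n = prof.size(), nb = vox0.n_elem;
  const uword np1 = qmat.n_cols;
  std::vector<mat> ps(n);
  for (uword s = 0; s < n; ++s) ps[s] = Rcpp::as<mat>(prof[s]);
  const uword V = ps[0].n_rows;
  mat fmat(nb, np1, fill::value(datum::nan));
  uvec ok(nb, fill::zeros);
  mat M(n, V - 1);

  for (uword k = 0; k < nb; ++k) {
    const uword self = static_cast<uword>(vox0[k]);
    for (uword s = 0; s < n; ++s) {
      const double* col = ps[s].colptr(k);
      uword jj = 0;
      for (uword j = 0; j < V; ++j) {
        if (j == self) continue;
        M(s, jj++) = col[j];
      }
    }
    // row-standardize profiles (zero mean, unit norm)
    vec rm = mean(M, 1);
    M.each_col() -= rm;
    vec nrm = sqrt(sum(square(M), 1));
    if (nrm.min() <= 0) continue;     // degenerate profile: flag missing
    M.each_col() /= nrm;
    mat R = M * M.t();
    R = clamp(R, -1.0, 1.0);
    // Gower centering: G = C R C
    vec rmean = mean(R, 1);
    double gmean = mean(rmean);
    mat G = R;
    G.each_col() -= rmean;
    G.each_row() -= rmean.t();
    G += gmean;
    G = 0.5 * (G + G.t());
    const double tr_g = trace(G);
    const double tr_h0g = accu((G * qz) % qz);
    rowvec s_q = sum((G * qmat) % qmat, 0);
    rowvec den = (tr_g - tr_h0g - s_q) / static_cast<double>(n_minus_p);
    if (!std::isfinite(den[0]) || den[0] <= 1e-12) continue;
    fmat.row(k) = s_q / den;
    ok[k] = 1;
  }
  return Rcpp::List::create(Rcpp::Named("f") = fmat,
                            Rcpp::Named("ok") = ok);
}
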