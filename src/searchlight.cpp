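#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// PCA compression over searchlight spheres.
//
// betas: trials x in-mask-voxels matrix; vox_xyz: 0-based voxel coordinates
// of each beta column in the 3-D volume; dim: volume dimensions; offsets:
// integer sphere offsets (including the center). For each in-mask center,
// the sphere is truncated to in-mask voxels; if at least min_sphere voxels
// remain, the trials x sphere matrix is mean-centered per voxel and the
// number of principal components k needed to reach var_threshold of the
// variance is found from the eigenvalues of the trial-space Gram matrix
// (identical to SVD of the centered matrix). compression = 1 - k/n.
// [[Rcpp::export(name = ".searchlight_compression_cpp")]]
List searchlight_compression_cpp(const arma::mat& betas,
                                 const IntegerMatrix& vox_xyz,
                                 const IntegerVector& dim,
                                 const IntegerMatrix& offsets,
                                 double var_threshold, int min_sphere) {
  const int n = (int) betas.n_rows;
  const int V = (int) betas.n_cols;
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if (vox_xyz.nrow() != V) stop("vox_xyz must have one row per beta column");

  // volume lookup: voxel -> beta column (or -1)
  std::vector<int> lut((size_t) nx * ny * nz, -1);
  for (int v = 0; v < V; ++v) {
    int x = vox_xyz(v, 0), y = vox_xyz(v, 1), z = vox_xyz(v, 2);
    lut[(size_t) x + nx * ((size_t) y + (size_t) ny * z)] = v;
  }

  const int n_off = offsets.nrow();
  NumericVector compression(V, NA_REAL);
  IntegerVector k_out(V, NA_INTEGER), sphere_size(V);
  std::vector<int> cols;
  cols.reserve(n_off);

  for (int c = 0; c < V; ++c) {
    const int cx = vox_xyz(c, 0), cy = vox_xyz(c, 1), cz = vox_xyz(c, 2);
    cols.clear();
    for (int o = 0; o < n_off; ++o) {
      int x = cx + offsets(o, 0), y = cy + offsets(o, 1),
          z = cz + offsets(o, 2);
      if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) continue;
      int col = lut[(size_t) x + nx * ((size_t) y + (size_t) ny * z)];
      if (col >= 0) cols.push_back(col);
    }
    sphere_size[c] = (int) cols.size();
    if ((int) cols.size() < min_sphere) continue;

    arma::uvec idx(cols.size());
    for (size_t j = 0; j < cols.size(); ++j) idx[j] = (arma::uword) cols[j];
    arma::mat X = betas.cols(idx);
    X.each_row() -= arma::mean(X, 0);

    arma::mat G = X * X.t();
    arma::vec eval;
    arma::eig_sym(eval, G);           // ascending
    double total = arma::accu(arma::clamp(eval, 0.0, arma::datum::inf));
    int k;
    if (total <= 0.0) {
      k = 1;                          // zero-variance sphere, by convention
    } else {
      double cum = 0.0;
      k = n;
      for (int j = (int) eval.n_elem - 1, cnt = 1; j >= 0; --j, ++cnt) {
        cum += std::max(eval[j], 0.0);
        if (cum / total >= var_threshold - 1e-12) { k = cnt; break; }
      }
    }
    k_out[c] = k;
    compression[c] = 1.0 - (double) k / n;
  }

  return List::create(_["compression"] = compression, _["k"] = k_out,
                      _["sphere_size"] = sphere_size);
}
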