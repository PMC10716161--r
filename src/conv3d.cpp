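#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D "same" correlation over a voxel grid, channels-last matrices.
// X: (nvox x Cin); W: (ntap*Cin x Cout), tap fastest within channel;
// idx: 1-based gather indices (nvox*ntap) into the zero-padded volume;
// center: 1-based positions of the voxels inside the padded volume.

// [[Rcpp::export]]
NumericMatrix cpp_conv3d_fwd(const NumericMatrix& X, const IntegerVector& idx,
                             const IntegerVector& center, int npad,
                             const NumericMatrix& W, const NumericVector& b) {
  const int nvox = X.nrow(), cin = X.ncol(), cout = W.ncol();
  const int ntap = W.nrow() / cin;
  NumericMatrix out(nvox, cout);
  std::vector<double> pad((size_t)npad, 0.0);
  std::vector<double> g((size_t)nvox);
  for (int co = 0; co < cout; ++co) {
    double* o = &out(0, co);
    const double bv = b[co];
    for (int v = 0; v < nvox; ++v) o[v] = bv;
  }
  for (int ci = 0; ci < cin; ++ci) {
    const double* xc = &X(0, ci);
    for (int v = 0; v < nvox; ++v) pad[center[v] - 1] = xc[v];
    for (int k = 0; k < ntap; ++k) {
      const int* id = &idx[(size_t)k * nvox];
      for (int v = 0; v < nvox; ++v) g[v] = pad[id[v] - 1];
      const int wrow = ci * ntap + k;
      for (int co = 0; co < cout; ++co) {
        const double w = W(wrow, co);
        if (w == 0.0) continue;
        double* o = &out(0, co);
        for (int v = 0; v < nvox; ++v) o[v] += w * g[v];
      }
    }
    // reset only the written entries for the next channel
    if (ci + 1 < cin) {
      for (int v = 0; v < nvox; ++v) pad[center[v] - 1] = 0.0;
    }
  }
  return out;
}

// weight gradient: crossprod(im2col(X), gY) without forming the matrix
// [[Rcpp::export]]
NumericMatrix cpp_conv3d_gw(const NumericMatrix& X, const IntegerVector& idx,
                            const IntegerVector& center, int npad,
                            const NumericMatrix& gY) {
  const int nvox = X.nrow(), cin = X.ncol(), cout = gY.ncol();
  const int ntap = idx.size() / nvox;
  NumericMatrix gW(ntap * cin, cout);
  std::vector<double> pad((size_t)npad, 0.0);
  std::vector<double> g((size_t)nvox);
  for (int ci = 0; ci < cin; ++ci) {
    const double* xc = &X(0, ci);
    for (int v = 0; v < nvox; ++v) pad[center[v] - 1] = xc[v];
    for (int k = 0; k < ntap; ++k) {
      const int* id = &idx[(size_t)k * nvox];
      for (int v = 0; v < nvox; ++v) g[v] = pad[id[v] - 1];
      const int wrow = ci * ntap + k;
      for (int co = 0; co < cout; ++co) {
        const double* gy = &gY(0, co);
        double acc = 0.0;
        for (int v = 0; v < nvox; ++v) acc += g[v] * gy[v];
        gW(wrow, co) = acc;
      }
    }
    if (ci + 1 < cin) {
      for (int v = 0; v < nvox; ++v) pad[center[v] - 1] = 0.0;
    }
  }
  return gW;
}
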