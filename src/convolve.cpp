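#include <Rcpp.h>
using namespace Rcpp;

// Reflect an index into [0, n-1] by mirroring about the edge samples
// (no edge duplication: -1 -> 1, n -> n-2), folding as often as needed.
static inline int reflect_index(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * (n - 1);
  i = i % period;
  if (i < 0) i += period;
  if (i >= n) i = period - i;
  return i;
}

// Correlate-with-flipped-kernel convolution along one axis of a 3D array.
// kernel has odd length 2r+1, centre at index r; axis is 0 (X), 1 (Y), 2 (Z).
// out[i] = sum_u in[i - u] * k[u], u = -r..r (true convolution).
// [[Rcpp::export(name = ".conv3d_axis")]]
NumericVector conv3d_axis(NumericVector vol, IntegerVector dims,
                          NumericVector kernel, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int klen = kernel.size();
  const int r = (klen - 1) / 2;
  NumericVector out(vol.size());

  const int n_axis = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  // strides of column-major [x, y, z]
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const R_xlen_t stride = (axis == 0) ? sx : (axis == 1) ? sy : sz;

  // iterate over all lines along `axis`
  const int nu = (axis == 0) ? ny : nx;
  const int nv = (axis == 2) ? ny : nz;
  const R_xlen_t su = (axis == 0) ? sy : sx;
  const R_xlen_t sv = (axis == 2) ? sy : sz;

  std::vector<double> line(n_axis);
  for (int v = 0; v < nv; ++v) {
    for (int u = 0; u < nu; ++u) {
      const R_xlen_t base = u * su + v * sv;
      for (int i = 0; i < n_axis; ++i) line[i] = vol[base + i * stride];
      for (int i = 0; i < n_axis; ++i) {
        double acc = 0.0;
        for (int j = 0; j < klen; ++j) {
          const int src = reflect_index(i - (j - r), n_axis);
          acc += line[src] * kernel[j];
        }
        out[base + i * stride] = acc;
      }
    }
  }
  return out;
}
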