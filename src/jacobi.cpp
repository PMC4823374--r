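#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Second-difference operator L along one axis with natural (free)
// boundaries: rows exist only where both neighbors do,
//   (Lf)_i = f_{i-1} + f_{i+1} - 2 f_i,  i = 1 .. n-2,
// so constant fields and linear ramps have exactly zero energy.  L^T is the
// adjoint.  Energy smoothed: E(f) = sum_a w_a ||L_a f||^2 with
// w_x = w_y = 1, w_z = 1/rho^4.

static void apply_L_line(const std::vector<double> &in,
                         std::vector<double> &out) {
  const int n = (int)in.size();
  std::fill(out.begin(), out.end(), 0.0);
  for (int i = 1; i < n - 1; ++i)
    out[i] = in[i - 1] + in[i + 1] - 2.0 * in[i];
}

static void apply_Lt_line(const std::vector<double> &g,
                          std::vector<double> &out) {
  const int n = (int)g.size();
  std::fill(out.begin(), out.end(), 0.0);
  for (int i = 1; i < n - 1; ++i) {
    out[i - 1] += g[i];
    out[i]     -= 2.0 * g[i];
    out[i + 1] += g[i];
  }
}

// accumulate w * L^T L f along `axis` into acc
static void accum_LtL(const NumericVector &f, NumericVector &acc,
                      const int *dims, int axis, double w) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const int n_axis = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  const R_xlen_t stride = (axis == 0) ? sx : (axis == 1) ? sy : sz;
  const int nu = (axis == 0) ? ny : nx;
  const int nv = (axis == 2) ? ny : nz;
  const R_xlen_t su = (axis == 0) ? sy : sx;
  const R_xlen_t sv = (axis == 2) ? sy : sz;

  std::vector<double> line(n_axis), tmp(n_axis), tmp2(n_axis);
  for (int v = 0; v < nv; ++v) {
    for (int u = 0; u < nu; ++u) {
      const R_xlen_t base = u * su + v * sv;
      for (int i = 0; i < n_axis; ++i) line[i] = f[base + i * stride];
      apply_L_line(line, tmp);
      apply_Lt_line(tmp, tmp2);
      for (int i = 0; i < n_axis; ++i) acc[base + i * stride] += w * tmp2[i];
    }
  }
}

// per-position diagonal of L^T L along an axis of length n
static std::vector<double> LtL_diag(int n) {
  std::vector<double> d(n, 0.0);
  for (int i = 1; i < n - 1; ++i) {
    d[i - 1] += 1.0; d[i] += 4.0; d[i + 1] += 1.0;
  }
  return d;
}

// [[Rcpp::export(name = ".smooth_energy")]]
double smooth_energy(NumericVector f, IntegerVector dims, double wz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double w[3] = {1.0, 1.0, wz};
  double e = 0.0;
  for (int axis = 0; axis < 3; ++axis) {
    const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
    const int n_axis = (axis == 0) ? nx : (axis == 1) ? ny : nz;
    const R_xlen_t stride = (axis == 0) ? sx : (axis == 1) ? sy : sz;
    const int nu = (axis == 0) ? ny : nx;
    const int nv = (axis == 2) ? ny : nz;
    const R_xlen_t su = (axis == 0) ? sy : sx;
    const R_xlen_t sv = (axis == 2) ? sy : sz;
    std::vector<double> line(n_axis), tmp(n_axis);
    for (int v = 0; v < nv; ++v)
      for (int u = 0; u < nu; ++u) {
        const R_xlen_t base = u * su + v * sv;
        for (int i = 0; i < n_axis; ++i) line[i] = f[base + i * stride];
        apply_L_line(line, tmp);
        for (int i = 0; i < n_axis; ++i) e += w[axis] * tmp[i] * tmp[i];
      }
  }
  return e;
}

// Projected (damped) Jacobi minimization of E(f) subject to v_i f_i >= m_i.
// Initialization f = v; after every sweep, violated constraints are reset to
// f_i = v_i * m_i.  Stops when the max absolute update < tol.
// [[Rcpp::export(name = ".jacobi_smooth")]]
List jacobi_smooth(NumericVector v, NumericVector m, IntegerVector dims,
                   double wz, double tol, int max_iter, double omega) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int d[3] = {nx, ny, nz};

  NumericVector f = clone(v);
  std::vector<double> dx = LtL_diag(nx), dy = LtL_diag(ny), dz = LtL_diag(nz);

  int it = 0;
  bool converged = false;
  NumericVector grad(n);
  for (it = 1; it <= max_iter; ++it) {
    std::fill(grad.begin(), grad.end(), 0.0);
    accum_LtL(f, grad, d, 0, 1.0);
    accum_LtL(f, grad, d, 1, 1.0);
    accum_LtL(f, grad, d, 2, wz);
    double maxdelta = 0.0;
    R_xlen_t idx = 0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x, ++idx) {
          double diag = dx[x] + dy[y] + wz * dz[z];
          if (diag <= 0) continue;             // 1x1x1 degenerate line
          double delta = -omega * grad[idx] / diag;
          double fnew = f[idx] + delta;
          // projection onto v_i f_i >= m_i
          if (v[idx] * fnew < m[idx]) fnew = v[idx] * m[idx];
          double ad = std::fabs(fnew - f[idx]);
          if (ad > maxdelta) maxdelta = ad;
          f[idx] = fnew;
        }
    if (maxdelta < tol) { converged = true; break; }
  }
  f.attr("dim") = dims;
  return List::create(_["f"] = f,
                      _["iterations"] = std::min(it, max_iter),
                      _["converged"] = converged);
}
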