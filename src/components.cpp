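#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Connected components of (mask != 0) under 6- or 26-connectivity.
// Returns an integer volume of component ids (0 = not in mask); component
// sizes are attached as attribute "sizes" (ordered by id).
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(IntegerVector mask, IntegerVector dims,
                               int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out(n, 0);

  std::vector<std::array<int, 3>> offs;
  if (connectivity == 6) {
    offs = {{{1,0,0}},{{-1,0,0}},{{0,1,0}},{{0,-1,0}},{{0,0,1}},{{0,0,-1}}};
  } else {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          if (dx || dy || dz) offs.push_back({{dx, dy, dz}});
  }

  std::vector<int> sizes;
  int next_id = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || out[s] != 0) continue;
    ++next_id;
    int sz = 0;
    stack.clear();
    stack.push_back(s);
    out[s] = next_id;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      ++sz;
      const int x = cur % nx;
      const int y = (cur / nx) % ny;
      const int z = cur / ((R_xlen_t)nx * ny);
      for (const auto &o : offs) {
        const int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const R_xlen_t q = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[q] != 0 && out[q] == 0) {
          out[q] = next_id;
          stack.push_back(q);
        }
      }
    }
    sizes.push_back(sz);
  }
  out.attr("dim") = dims;
  out.attr("sizes") = wrap(sizes);
  return out;
}
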