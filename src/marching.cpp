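#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// Zero level set extraction by marching tetrahedra: each grid cell is split
// into 6 tetrahedra sharing the main diagonal, and the f = 0 surface is
// triangulated inside each tetrahedron.  Voxels with f > 0 are inside the
// object.  Vertices are deduplicated per cut grid edge, so the mesh is
// watertight wherever the positive region does not touch the volume border.

struct V3 { double x, y, z; };

static inline V3 sub(const V3 &a, const V3 &b) { return {a.x-b.x, a.y-b.y, a.z-b.z}; }
static inline V3 cross(const V3 &a, const V3 &b) {
  return {a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x};
}
static inline double dot(const V3 &a, const V3 &b) { return a.x*b.x + a.y*b.y + a.z*b.z; }

// [[Rcpp::export(name = ".marching_tetrahedra")]]
List marching_tetrahedra(NumericVector f, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto lin = [&](int x, int y, int z) -> R_xlen_t {
    return x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
  };
  // cube corner offsets, bit0 = x, bit1 = y, bit2 = z
  const int cx[8] = {0,1,0,1,0,1,0,1};
  const int cy[8] = {0,0,1,1,0,0,1,1};
  const int cz[8] = {0,0,0,0,1,1,1,1};
  // 6 tetrahedra around the 0-7 diagonal
  const int tets[6][4] = {
    {0,1,3,7}, {0,3,2,7}, {0,2,6,7}, {0,6,4,7}, {0,4,5,7}, {0,5,1,7}
  };

  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  std::unordered_map<uint64_t, int> edge_vertex;

  auto edge_vert = [&](R_xlen_t gp, R_xlen_t gq, const V3 &pp, const V3 &pq,
                       double fp, double fq) -> int {
    uint64_t a = (uint64_t)std::min(gp, gq), b = (uint64_t)std::max(gp, gq);
    uint64_t key = a * 0x100000000ULL ^ b;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    // interpolate from the positive end for sign consistency
    double t = fp / (fp - fq);       // fp > 0 >= fq, so t in (0, 1]
    V3 p = {pp.x + t * (pq.x - pp.x), pp.y + t * (pq.y - pp.y),
            pp.z + t * (pq.z - pp.z)};
    int id = (int)vx.size();
    vx.push_back(p.x); vy.push_back(p.y); vz.push_back(p.z);
    edge_vertex.emplace(key, id);
    return id;
  };

  auto add_tri = [&](int a, int b, int c, const V3 &outward_ref,
                     const V3 &inward_ref) {
    V3 A = {vx[a], vy[a], vz[a]}, B = {vx[b], vy[b], vz[b]},
       C = {vx[c], vy[c], vz[c]};
    V3 nrm = cross(sub(B, A), sub(C, A));
    V3 dir = sub(outward_ref, inward_ref);   // inside -> outside
    if (dot(nrm, dir) < 0) std::swap(b, c);
    tri.push_back(a); tri.push_back(b); tri.push_back(c);
  };

  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        double fv[8]; R_xlen_t gi[8]; V3 pos[8];
        bool any_pos = false, any_neg = false;
        for (int c = 0; c < 8; ++c) {
          const int xx = x + cx[c], yy = y + cy[c], zz = z + cz[c];
          gi[c] = lin(xx, yy, zz);
          fv[c] = f[gi[c]];
          pos[c] = {(double)xx, (double)yy, (double)zz};
          (fv[c] > 0 ? any_pos : any_neg) = true;
        }
        if (!any_pos || !any_neg) continue;
        for (int t = 0; t < 6; ++t) {
          int P[4], N[4], np = 0, nn = 0;
          for (int k = 0; k < 4; ++k) {
            int c = tets[t][k];
            if (fv[c] > 0) P[np++] = c; else N[nn++] = c;
          }
          if (np == 0 || np == 4) continue;
          // reference points for orientation
          V3 pin = {0,0,0}, pout = {0,0,0};
          for (int k = 0; k < np; ++k) { pin.x += pos[P[k]].x; pin.y += pos[P[k]].y; pin.z += pos[P[k]].z; }
          for (int k = 0; k < nn; ++k) { pout.x += pos[N[k]].x; pout.y += pos[N[k]].y; pout.z += pos[N[k]].z; }
          pin.x /= np; pin.y /= np; pin.z /= np;
          pout.x /= nn; pout.y /= nn; pout.z /= nn;
          if (np == 1) {
            int a = edge_vert(gi[P[0]], gi[N[0]], pos[P[0]], pos[N[0]], fv[P[0]], fv[N[0]]);
            int b = edge_vert(gi[P[0]], gi[N[1]], pos[P[0]], pos[N[1]], fv[P[0]], fv[N[1]]);
            int c = edge_vert(gi[P[0]], gi[N[2]], pos[P[0]], pos[N[2]], fv[P[0]], fv[N[2]]);
            add_tri(a, b, c, pout, pin);
          } else if (np == 3) {
            int a = edge_vert(gi[P[0]], gi[N[0]], pos[P[0]], pos[N[0]], fv[P[0]], fv[N[0]]);
            int b = edge_vert(gi[P[1]], gi[N[0]], pos[P[1]], pos[N[0]], fv[P[1]], fv[N[0]]);
            int c = edge_vert(gi[P[2]], gi[N[0]], pos[P[2]], pos[N[0]], fv[P[2]], fv[N[0]]);
            add_tri(a, b, c, pout, pin);
          } else { // np == 2: quad from the four positive-negative edges
            int v11 = edge_vert(gi[P[0]], gi[N[0]], pos[P[0]], pos[N[0]], fv[P[0]], fv[N[0]]);
            int v12 = edge_vert(gi[P[0]], gi[N[1]], pos[P[0]], pos[N[1]], fv[P[0]], fv[N[1]]);
            int v22 = edge_vert(gi[P[1]], gi[N[1]], pos[P[1]], pos[N[1]], fv[P[1]], fv[N[1]]);
            int v21 = edge_vert(gi[P[1]], gi[N[0]], pos[P[1]], pos[N[0]], fv[P[1]], fv[N[0]]);
            add_tri(v11, v12, v22, pout, pin);
            add_tri(v11, v22, v21, pout, pin);
          }
        }
      }

  const int nvert = (int)vx.size();
  NumericMatrix verts(nvert, 3);
  for (int i = 0; i < nvert; ++i) {
    verts(i, 0) = vx[i]; verts(i, 1) = vy[i]; verts(i, 2) = vz[i];
  }
  const int nface = (int)tri.size() / 3;
  IntegerMatrix faces(nface, 3);
  for (int i = 0; i < nface; ++i) {
    faces(i, 0) = tri[3*i] + 1; faces(i, 1) = tri[3*i+1] + 1;
    faces(i, 2) = tri[3*i+2] + 1;
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}
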