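// Isosurface extraction from a regular scalar grid by marching tetrahedra:
// each grid cube is split into the six tetrahedra sharing the main diagonal,
// and the iso-level crossing of every tetrahedron is triangulated with
// linear interpolation along the edges.  Vertices are deduplicated by the
// grid edge they lie on, so shared faces stitch exactly.
#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

namespace {

struct MeshAcc {
  std::vector<double> verts;              // x,y,z triples
  std::vector<int> faces;                 // 0-based vertex indices
  std::unordered_map<uint64_t, int> edge_vert;
};

// interpolated vertex on the grid edge (ia, ib); returns 0-based index
int edge_vertex(MeshAcc& acc, uint64_t ia, uint64_t ib, const double* pa,
                const double* pb, double va, double vb, double level) {
  if (ia > ib) {
    std::swap(ia, ib);
    std::swap(pa, pb);
    std::swap(va, vb);
  }
  uint64_t key = ia * 0x100000000ULL ^ ib;
  auto it = acc.edge_vert.find(key);
  if (it != acc.edge_vert.end()) return it->second;
  double denom = vb - va;
  double s = std::abs(denom) < 1e-300 ? 0.5 : (level - va) / denom;
  s = s < 0.0 ? 0.0 : (s > 1.0 ? 1.0 : s);
  int id = (int)(acc.verts.size() / 3);
  for (int k = 0; k < 3; ++k) {
    acc.verts.push_back(pa[k] + s * (pb[k] - pa[k]));
  }
  acc.edge_vert.emplace(key, id);
  return id;
}

} // namespace

// grid: numeric array (nx, ny, nz), value[i,j,k] at position
// origin + (i-1, j-1, k-1) * spacing (R is 1-based).
// [[Rcpp::export]]
List cpp_marching_tetrahedra(NumericVector grid, NumericVector origin,
                             NumericVector spacing, double level) {
  IntegerVector dim = grid.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  auto gid = [&](int i, int j, int k) -> uint64_t {
    return (uint64_t)i + (uint64_t)nx * ((uint64_t)j + (uint64_t)ny * k);
  };
  // six tetrahedra sharing the 0-7 diagonal; cube corners indexed by bits
  // (x = bit0, y = bit1, z = bit2)
  static const int tets[6][4] = {{0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
                                 {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
  MeshAcc acc;
  double cpos[8][3];
  double cval[8];
  uint64_t cid[8];
  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_lo = false, any_hi = false;
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          cid[c] = gid(ci, cj, ck);
          cval[c] = grid[cid[c]];
          cpos[c][0] = origin[0] + ci * spacing[0];
          cpos[c][1] = origin[1] + cj * spacing[1];
          cpos[c][2] = origin[2] + ck * spacing[2];
          (cval[c] >= level ? any_hi : any_lo) = true;
        }
        if (!any_lo || !any_hi) continue;
        for (int t = 0; t < 6; ++t) {
          int v[4];
          int inside = 0;
          for (int c = 0; c < 4; ++c) {
            v[c] = tets[t][c];
            if (cval[v[c]] >= level) ++inside;
          }
          if (inside == 0 || inside == 4) continue;
          // collect inside/outside corner slots
          int in_idx[4], out_idx[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            if (cval[v[c]] >= level) in_idx[ni++] = v[c];
            else out_idx[no++] = v[c];
          }
          auto ev = [&](int a, int b) {
            return edge_vertex(acc, cid[a], cid[b], cpos[a], cpos[b], cval[a],
                               cval[b], level);
          };
          if (ni == 1) {
            int a = in_idx[0];
            int p0 = ev(a, out_idx[0]), p1 = ev(a, out_idx[1]),
                p2 = ev(a, out_idx[2]);
            acc.faces.insert(acc.faces.end(), {p0, p1, p2});
          } else if (ni == 3) {
            int a = out_idx[0];
            int p0 = ev(a, in_idx[0]), p1 = ev(a, in_idx[1]),
                p2 = ev(a, in_idx[2]);
            acc.faces.insert(acc.faces.end(), {p0, p1, p2});
          } else { // 2 in, 2 out: quad split into two triangles
            int a0 = in_idx[0], a1 = in_idx[1], b0 = out_idx[0],
                b1 = out_idx[1];
            int p00 = ev(a0, b0), p01 = ev(a0, b1), p10 = ev(a1, b0),
                p11 = ev(a1, b1);
            acc.faces.insert(acc.faces.end(), {p00, p01, p11});
            acc.faces.insert(acc.faces.end(), {p00, p11, p10});
          }
        }
      }
    }
  }
  int nv = (int)(acc.verts.size() / 3), nf = (int)(acc.faces.size() / 3);
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int a = 0; a < nv; ++a) {
    for (int b = 0; b < 3; ++b) V(a, b) = acc.verts[3 * a + b];
  }
  for (int a = 0; a < nf; ++a) {
    for (int b = 0; b < 3; ++b) F(a, b) = acc.faces[3 * a + b] + 1; // 1-based
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
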