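#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Iso-surface triangulation by marching tetrahedra on the Freudenthal
// (6-tetrahedra) decomposition of each grid cube. The decomposition is
// face-to-face consistent across cubes, and interpolated edge vertices are
// welded through a shared edge->vertex map, so the result is watertight
// wherever the iso-surface does not reach the grid boundary (callers pad
// the field with background). Coordinates are 0-based grid indices; the R
// wrapper scales them into physical units.

struct V3 {
  double x, y, z;
};

// [[Rcpp::export(name = ".cpp_marching_tets")]]
List cpp_marching_tets(NumericVector field, IntegerVector dim, double iso) {
  const int ni = dim[0], nj = dim[1], nk = dim[2];
  const double* f = field.begin();
  auto val = [&](int i, int j, int k) -> double {
    return f[i + (long)ni * (j + (long)nj * k)];
  };
  auto gid = [&](int i, int j, int k) -> long {
    return i + (long)ni * (j + (long)nj * k);
  };

  // the 6 axis permutations defining the Freudenthal tetrahedra
  static const int perms[6][3] = {{0, 1, 2}, {0, 2, 1}, {1, 0, 2},
                                  {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};

  std::unordered_map<long long, int> edge_vertex;
  std::vector<V3> verts;
  std::vector<int> tris;  // 0-based vertex ids, groups of 3

  // interpolated vertex on grid edge (a, b); welded via map
  auto edge_point = [&](const int a[3], const int b[3]) -> int {
    long ga = gid(a[0], a[1], a[2]), gb = gid(b[0], b[1], b[2]);
    long lo = std::min(ga, gb), hi = std::max(ga, gb);
    long long key = lo * (long long)(ni * (long)nj * nk) + hi;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double va = val(a[0], a[1], a[2]), vb = val(b[0], b[1], b[2]);
    double t = (vb == va) ? 0.5 : (iso - va) / (vb - va);
    V3 p = {a[0] + t * (b[0] - a[0]), a[1] + t * (b[1] - a[1]),
            a[2] + t * (b[2] - a[2])};
    int id = (int)verts.size();
    verts.push_back(p);
    edge_vertex[key] = id;
    return id;
  };

  // emit triangle (p, q, r) oriented so its normal points from the
  // inside (value > iso) region toward the outside region
  auto emit = [&](int p, int q, int r, const V3& inside, const V3& outside) {
    const V3 &A = verts[p], &B = verts[q], &C = verts[r];
    double ux = B.x - A.x, uy = B.y - A.y, uz = B.z - A.z;
    double vx = C.x - A.x, vy = C.y - A.y, vz = C.z - A.z;
    double nx = uy * vz - uz * vy, ny = uz * vx - ux * vz,
           nz = ux * vy - uy * vx;
    double dx = outside.x - inside.x, dy = outside.y - inside.y,
           dz = outside.z - inside.z;
    if (nx * dx + ny * dy + nz * dz < 0) std::swap(q, r);
    tris.push_back(p);
    tris.push_back(q);
    tris.push_back(r);
  };

  int corner[4][3];
  for (int k = 0; k + 1 < nk; ++k)
    for (int j = 0; j + 1 < nj; ++j)
      for (int i = 0; i + 1 < ni; ++i) {
        // skip cubes entirely on one side of the iso-level
        bool any_in = false, any_out = false;
        for (int d = 0; d < 8; ++d) {
          double v = val(i + (d & 1), j + ((d >> 1) & 1), k + ((d >> 2) & 1));
          (v > iso ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;

        for (int p = 0; p < 6; ++p) {
          corner[0][0] = i; corner[0][1] = j; corner[0][2] = k;
          for (int s = 1; s < 4; ++s) {
            corner[s][0] = corner[s - 1][0];
            corner[s][1] = corner[s - 1][1];
            corner[s][2] = corner[s - 1][2];
            corner[s][perms[p][s - 1]] += 1;
          }
          bool in[4];
          int nin = 0;
          for (int s = 0; s < 4; ++s) {
            in[s] = val(corner[s][0], corner[s][1], corner[s][2]) > iso;
            if (in[s]) nin++;
          }
          if (nin == 0 || nin == 4) continue;

          int ins[4], outs[4], a = 0, b = 0;
          for (int s = 0; s < 4; ++s) (in[s] ? ins[a++] : outs[b++]) = s;
          V3 ci = {0, 0, 0}, co = {0, 0, 0};
          for (int s = 0; s < a; ++s) {
            ci.x += corner[ins[s]][0]; ci.y += corner[ins[s]][1];
            ci.z += corner[ins[s]][2];
          }
          for (int s = 0; s < b; ++s) {
            co.x += corner[outs[s]][0]; co.y += corner[outs[s]][1];
            co.z += corner[outs[s]][2];
          }
          ci.x /= a; ci.y /= a; ci.z /= a;
          co.x /= b; co.y /= b; co.z /= b;

          if (nin == 1) {
            int v0 = edge_point(corner[ins[0]], corner[outs[0]]);
            int v1 = edge_point(corner[ins[0]], corner[outs[1]]);
            int v2 = edge_point(corner[ins[0]], corner[outs[2]]);
            emit(v0, v1, v2, ci, co);
          } else if (nin == 3) {
            int v0 = edge_point(corner[ins[0]], corner[outs[0]]);
            int v1 = edge_point(corner[ins[1]], corner[outs[0]]);
            int v2 = edge_point(corner[ins[2]], corner[outs[0]]);
            emit(v0, v1, v2, ci, co);
          } else {  // nin == 2: quad split into two triangles
            int v0 = edge_point(corner[ins[0]], corner[outs[0]]);
            int v1 = edge_point(corner[ins[0]], corner[outs[1]]);
            int v2 = edge_point(corner[ins[1]], corner[outs[1]]);
            int v3 = edge_point(corner[ins[1]], corner[outs[0]]);
            emit(v0, v1, v2, ci, co);
            emit(v0, v2, v3, ci, co);
          }
        }
      }

  NumericMatrix V((int)verts.size(), 3);
  for (int v = 0; v < (int)verts.size(); ++v) {
    V(v, 0) = verts[v].x;
    V(v, 1) = verts[v].y;
    V(v, 2) = verts[v].z;
  }
  IntegerMatrix F((int)tris.size() / 3, 3);
  for (int t = 0; t < F.nrow(); ++t) {
    F(t, 0) = tris[3 * t] + 1;  // 1-based for R
    F(t, 1) = tris[3 * t + 1] + 1;
    F(t, 2) = tris[3 * t + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
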