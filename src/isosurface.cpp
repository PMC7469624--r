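#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Iso-surface extraction by marching tetrahedra on a rectilinear lattice.
// Each cell is split into 6 tetrahedra sharing the cell's main diagonal, so
// faces of neighbouring cells are triangulated consistently and the output
// surface is closed and manifold wherever the iso level avoids lattice values.
// Vertices lie on lattice edges (linear interpolation) and are deduplicated by
// the global index pair of the edge's end corners, which makes the mesh
// watertight by construction. Triangle orientation is decided combinatorially
// (permutation parity within a positively oriented tetrahedron), so it is
// consistent even for degenerate slivers.

static const int TET[6][4] = {
  {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
  {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}
};
// corner k offsets: bit0 -> x, bit1 -> y, bit2 -> z (corners 0..7, diagonal 0-6)
static const int OFF[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
};

struct MeshAcc {
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
  std::unordered_map<uint64_t, int> edge_vertex;
};

static int edge_point(MeshAcc &acc, uint64_t ga, uint64_t gb,
                      const double *pa, const double *pb,
                      double va, double vb, double level) {
  uint64_t a = ga, b = gb;
  const double *p1 = pa, *p2 = pb;
  double v1 = va, v2 = vb;
  if (a > b) { std::swap(a, b); std::swap(p1, p2); std::swap(v1, v2); }
  uint64_t key = a * 0x100000000ULL + b; // grid corner counts stay far below 2^32
  auto it = acc.edge_vertex.find(key);
  if (it != acc.edge_vertex.end()) return it->second;
  double t = (level - v1) / (v2 - v1);
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  int id = (int)acc.vx.size();
  acc.vx.push_back(p1[0] + t * (p2[0] - p1[0]));
  acc.vy.push_back(p1[1] + t * (p2[1] - p1[1]));
  acc.vz.push_back(p1[2] + t * (p2[2] - p1[2]));
  acc.edge_vertex.emplace(key, id);
  return id;
}

static inline bool perm4_even(int a, int b, int c, int d) {
  int p[4] = {a, b, c, d};
  int inv = 0;
  for (int i = 0; i < 4; ++i)
    for (int j = i + 1; j < 4; ++j)
      if (p[i] > p[j]) ++inv;
  return (inv % 2) == 0;
}

// [[Rcpp::export(name = ".mt_isosurface")]]
List mt_isosurface(NumericVector field, IntegerVector dims,
                   NumericVector spacing, NumericVector origin, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double *F = REAL(field);
  MeshAcc acc;

  // reorder each tetrahedron to positive orientation (constant per tet index
  // because all cells are congruent and spacing is positive)
  int L[6][4];
  for (int t = 0; t < 6; ++t) {
    for (int c = 0; c < 4; ++c) L[t][c] = TET[t][c];
    double e[3][3];
    for (int c = 1; c < 4; ++c)
      for (int d = 0; d < 3; ++d)
        e[c - 1][d] = OFF[L[t][c]][d] - OFF[L[t][0]][d];
    double det = e[0][0]*(e[1][1]*e[2][2]-e[1][2]*e[2][1])
               - e[0][1]*(e[1][0]*e[2][2]-e[1][2]*e[2][0])
               + e[0][2]*(e[1][0]*e[2][1]-e[1][1]*e[2][0]);
    if (det < 0) std::swap(L[t][2], L[t][3]);
  }

  // nudge values exactly at the level so inside/outside is strict
  double vmax = 0.0;
  const size_t N = (size_t)nx * ny * nz;
  for (size_t i = 0; i < N; ++i) {
    double a = std::fabs(F[i]);
    if (a > vmax) vmax = a;
  }
  const double nudge = 1e-9 * (vmax + std::fabs(level) + 1.0);

  double pos[8][3];
  double val[8];
  uint64_t gidx[8];

  auto emit = [&](int i, int j, int k) {
    acc.f0.push_back(i); acc.f1.push_back(j); acc.f2.push_back(k);
  };

  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      size_t base = (size_t)j * nx + (size_t)k * nx * ny;
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          size_t idx = base + i + OFF[c][0]
                     + (size_t)OFF[c][1] * nx
                     + (size_t)OFF[c][2] * nx * ny;
          double v = F[idx];
          if (v == level) v = level + nudge;
          val[c] = v;
          gidx[c] = (uint64_t)idx;
          if (v > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int c = 0; c < 8; ++c) {
          pos[c][0] = ox + sx * (i + OFF[c][0]);
          pos[c][1] = oy + sy * (j + OFF[c][1]);
          pos[c][2] = oz + sz * (k + OFF[c][2]);
        }
        for (int t = 0; t < 6; ++t) {
          int in_p[4], out_p[4];
          int nin = 0, nout = 0;
          for (int c = 0; c < 4; ++c) {
            int v = L[t][c];
            if (val[v] > level) in_p[nin++] = c; else out_p[nout++] = c;
          }
          if (nin == 0 || nin == 4) continue;
          auto EP = [&](int pa, int pb) {
            int a = L[t][pa], b = L[t][pb];
            return edge_point(acc, gidx[a], gidx[b], pos[a], pos[b],
                              val[a], val[b], level);
          };
          if (nin == 1) {
            bool even = perm4_even(in_p[0], out_p[0], out_p[1], out_p[2]);
            int e0 = EP(in_p[0], out_p[0]);
            int e1 = EP(in_p[0], out_p[1]);
            int e2 = EP(in_p[0], out_p[2]);
            if (even) emit(e0, e1, e2); else emit(e0, e2, e1);
          } else if (nin == 3) {
            bool even = perm4_even(out_p[0], in_p[0], in_p[1], in_p[2]);
            int e0 = EP(out_p[0], in_p[0]);
            int e1 = EP(out_p[0], in_p[1]);
            int e2 = EP(out_p[0], in_p[2]);
            if (even) emit(e0, e2, e1); else emit(e0, e1, e2);
          } else { // nin == 2
            bool even = perm4_even(in_p[0], in_p[1], out_p[0], out_p[1]);
            int eac = EP(in_p[0], out_p[0]);
            int ead = EP(in_p[0], out_p[1]);
            int ebc = EP(in_p[1], out_p[0]);
            int ebd = EP(in_p[1], out_p[1]);
            if (even) {
              emit(eac, ead, ebd); emit(eac, ebd, ebc);
            } else {
              emit(eac, ebd, ead); emit(eac, ebc, ebd);
            }
          }
        }
      }
    }
  }

  int nv = (int)acc.vx.size();
  int nf = (int)acc.f0.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix Fm(nf, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = acc.vx[i]; V(i, 1) = acc.vy[i]; V(i, 2) = acc.vz[i];
  }
  for (int i = 0; i < nf; ++i) {
    Fm(i, 0) = acc.f0[i] + 1; Fm(i, 1) = acc.f1[i] + 1; Fm(i, 2) = acc.f2[i] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}
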