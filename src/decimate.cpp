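#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Quadric error metric edge-collapse decimation (Garland-Heckbert style) for
// closed triangle meshes. Collapses are rejected when they would pinch the
// mesh (link condition) or flip a surviving face normal, so watertightness
// and orientation are preserved.

namespace {

struct Quadric {
  double q[10]; // symmetric 4x4: [a2 ab ac ad b2 bc bd c2 cd d2]
  Quadric() { std::fill(q, q + 10, 0.0); }
  void add_plane(double a, double b, double c, double d, double w) {
    q[0] += w * a * a; q[1] += w * a * b; q[2] += w * a * c; q[3] += w * a * d;
    q[4] += w * b * b; q[5] += w * b * c; q[6] += w * b * d;
    q[7] += w * c * c; q[8] += w * c * d; q[9] += w * d * d;
  }
  Quadric operator+(const Quadric &o) const {
    Quadric r;
    for (int i = 0; i < 10; ++i) r.q[i] = q[i] + o.q[i];
    return r;
  }
  double eval(const double p[3]) const {
    double x = p[0], y = p[1], z = p[2];
    return q[0]*x*x + 2*q[1]*x*y + 2*q[2]*x*z + 2*q[3]*x
         + q[4]*y*y + 2*q[5]*y*z + 2*q[6]*y
         + q[7]*z*z + 2*q[8]*z + q[9];
  }
  // minimize the quadric; false if the 3x3 system is near-singular
  bool optimum(double out[3]) const {
    double A[3][3] = {{q[0], q[1], q[2]}, {q[1], q[4], q[5]}, {q[2], q[5], q[7]}};
    double b[3] = {-q[3], -q[6], -q[8]};
    double det = A[0][0]*(A[1][1]*A[2][2]-A[1][2]*A[2][1])
               - A[0][1]*(A[1][0]*A[2][2]-A[1][2]*A[2][0])
               + A[0][2]*(A[1][0]*A[2][1]-A[1][1]*A[2][0]);
    double scale = 0.0;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) scale = std::max(scale, std::fabs(A[i][j]));
    if (scale <= 0.0 || std::fabs(det) < 1e-10 * scale * scale * scale) return false;
    // Cramer's rule
    for (int c = 0; c < 3; ++c) {
      double M[3][3];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) M[i][j] = (j == c) ? b[i] : A[i][j];
      double dc = M[0][0]*(M[1][1]*M[2][2]-M[1][2]*M[2][1])
                - M[0][1]*(M[1][0]*M[2][2]-M[1][2]*M[2][0])
                + M[0][2]*(M[1][0]*M[2][1]-M[1][1]*M[2][0]);
      out[c] = dc / det;
    }
    return true;
  }
};

struct Candidate {
  double cost;
  int v1, v2;
  unsigned gen1, gen2;
  double pos[3];
  bool operator<(const Candidate &o) const { return cost > o.cost; } // min-heap
};

struct Mesh {
  std::vector<double> V;      // 3*nv
  std::vector<int> F;         // 3*nf
  std::vector<char> valive, falive;
  std::vector<std::vector<int>> vfaces;
  std::vector<Quadric> Q;
  std::vector<unsigned> gen;

  double *vp(int v) { return &V[3 * v]; }
  int fv(int f, int c) const { return F[3 * f + c]; }

  void face_normal(int f, double n[3], bool unit = true) const {
    const double *a = &V[3 * F[3*f]], *b = &V[3 * F[3*f+1]], *c = &V[3 * F[3*f+2]];
    double u[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
    double w[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
    n[0] = u[1]*w[2]-u[2]*w[1]; n[1] = u[2]*w[0]-u[0]*w[2]; n[2] = u[0]*w[1]-u[1]*w[0];
    if (unit) {
      double l = std::sqrt(n[0]*n[0]+n[1]*n[1]+n[2]*n[2]);
      if (l > 0) { n[0] /= l; n[1] /= l; n[2] /= l; }
    }
  }

  void neighbors(int v, std::vector<int> &out) const {
    out.clear();
    for (int f : vfaces[v]) {
      if (!falive[f]) continue;
      for (int c = 0; c < 3; ++c) {
        int u = fv(f, c);
        if (u != v && std::find(out.begin(), out.end(), u) == out.end())
          out.push_back(u);
      }
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".qem_decimate")]]
List qem_decimate(NumericMatrix vertices, IntegerMatrix faces, int target_faces) {
  Mesh m;
  const int nv = vertices.nrow(), nf = faces.nrow();
  m.V.resize(3 * (size_t)nv);
  for (int i = 0; i < nv; ++i)
    for (int c = 0; c < 3; ++c) m.V[3*i+c] = vertices(i, c);
  m.F.resize(3 * (size_t)nf);
  for (int i = 0; i < nf; ++i)
    for (int c = 0; c < 3; ++c) m.F[3*i+c] = faces(i, c) - 1;
  m.valive.assign(nv, 1);
  m.falive.assign(nf, 1);
  m.vfaces.assign(nv, {});
  m.gen.assign(nv, 0);
  for (int f = 0; f < nf; ++f)
    for (int c = 0; c < 3; ++c) m.vfaces[m.fv(f, c)].push_back(f);

  // initial quadrics: area-weighted face planes
  m.Q.assign(nv, Quadric());
  for (int f = 0; f < nf; ++f) {
    double n[3];
    m.face_normal(f, n, false);
    double area2 = std::sqrt(n[0]*n[0]+n[1]*n[1]+n[2]*n[2]);
    if (area2 <= 0) continue;
    double nn[3] = {n[0]/area2, n[1]/area2, n[2]/area2};
    const double *a = &m.V[3 * m.fv(f, 0)];
    double d = -(nn[0]*a[0] + nn[1]*a[1] + nn[2]*a[2]);
    for (int c = 0; c < 3; ++c)
      m.Q[m.fv(f, c)].add_plane(nn[0], nn[1], nn[2], d, area2 / 2.0);
  }

  std::priority_queue<Candidate> heap;
  auto push_edge = [&](int v1, int v2) {
    if (v1 > v2) std::swap(v1, v2);
    Quadric q = m.Q[v1] + m.Q[v2];
    Candidate c;
    c.v1 = v1; c.v2 = v2; c.gen1 = m.gen[v1]; c.gen2 = m.gen[v2];
    const double *p1 = m.vp(v1), *p2 = m.vp(v2);
    double mid[3] = {(p1[0]+p2[0])/2, (p1[1]+p2[1])/2, (p1[2]+p2[2])/2};
    double el2 = (p1[0]-p2[0])*(p1[0]-p2[0]) + (p1[1]-p2[1])*(p1[1]-p2[1])
               + (p1[2]-p2[2])*(p1[2]-p2[2]);
    double best[3];
    bool have = q.optimum(best);
    if (have) {
      // ill-conditioned quadrics can park the optimum far from the edge;
      // keep it only if it stays within a couple of edge lengths
      double d2 = (best[0]-mid[0])*(best[0]-mid[0]) + (best[1]-mid[1])*(best[1]-mid[1])
                + (best[2]-mid[2])*(best[2]-mid[2]);
      if (d2 > 4.0 * el2 + 1e-12) have = false;
    }
    if (!have) {
      const double *cands[3] = {mid, p1, p2};
      double bc = R_PosInf;
      for (int i = 0; i < 3; ++i) {
        double e = q.eval(cands[i]);
        if (e < bc) { bc = e; best[0]=cands[i][0]; best[1]=cands[i][1]; best[2]=cands[i][2]; }
      }
    }
    c.pos[0] = best[0]; c.pos[1] = best[1]; c.pos[2] = best[2];
    c.cost = q.eval(best);
    heap.push(c);
  };

  std::vector<int> nb;
  for (int v = 0; v < nv; ++v) {
    m.neighbors(v, nb);
    for (int u : nb) if (u > v) push_edge(v, u);
  }

  int live_faces = nf;
  std::vector<int> nb1, nb2, shared_faces;

  while (live_faces > target_faces && !heap.empty()) {
    Candidate c = heap.top();
    heap.pop();
    int v1 = c.v1, v2 = c.v2;
    if (!m.valive[v1] || !m.valive[v2]) continue;
    if (c.gen1 != m.gen[v1] || c.gen2 != m.gen[v2]) continue;

    // still an edge?
    shared_faces.clear();
    for (int f : m.vfaces[v1]) {
      if (!m.falive[f]) continue;
      for (int cc = 0; cc < 3; ++cc)
        if (m.fv(f, cc) == v2) { shared_faces.push_back(f); break; }
    }
    if (shared_faces.size() != 2) continue; // boundary or non-manifold: skip

    // link condition: common neighbors must be exactly the two opposite verts
    m.neighbors(v1, nb1);
    m.neighbors(v2, nb2);
    int common = 0;
    for (int u : nb1)
      if (u != v2 && std::find(nb2.begin(), nb2.end(), u) != nb2.end()) ++common;
    if (common != 2) continue;

    // normal-flip / degeneracy guard on surviving faces
    double old1[3] = {m.vp(v1)[0], m.vp(v1)[1], m.vp(v1)[2]};
    double old2[3] = {m.vp(v2)[0], m.vp(v2)[1], m.vp(v2)[2]};
    bool ok = true;
    for (int pass = 0; pass < 2 && ok; ++pass) {
      int v = pass == 0 ? v1 : v2;
      for (int f : m.vfaces[v]) {
        if (!m.falive[f]) continue;
        if (std::find(shared_faces.begin(), shared_faces.end(), f) != shared_faces.end()) continue;
        double n0[3];
        m.face_normal(f, n0);
        double save[3] = {m.vp(v)[0], m.vp(v)[1], m.vp(v)[2]};
        m.vp(v)[0] = c.pos[0]; m.vp(v)[1] = c.pos[1]; m.vp(v)[2] = c.pos[2];
        double n1[3];
        m.face_normal(f, n1, false);
        double l1 = std::sqrt(n1[0]*n1[0]+n1[1]*n1[1]+n1[2]*n1[2]);
        double dot = n0[0]*n1[0]+n0[1]*n1[1]+n0[2]*n1[2];
        m.vp(v)[0] = save[0]; m.vp(v)[1] = save[1]; m.vp(v)[2] = save[2];
        if (l1 < 1e-12 || dot <= 1e-12) { ok = false; break; }
      }
    }
    if (!ok) continue;

    // collapse v2 -> v1 at c.pos
    m.vp(v1)[0] = c.pos[0]; m.vp(v1)[1] = c.pos[1]; m.vp(v1)[2] = c.pos[2];
    m.Q[v1] = m.Q[v1] + m.Q[v2];
    for (int f : shared_faces) {
      if (m.falive[f]) { m.falive[f] = 0; --live_faces; }
    }
    for (int f : m.vfaces[v2]) {
      if (!m.falive[f]) continue;
      for (int cc = 0; cc < 3; ++cc)
        if (m.F[3*f+cc] == v2) m.F[3*f+cc] = v1;
      m.vfaces[v1].push_back(f);
    }
    // drop dead faces from v1's incidence list so it stays O(degree)
    {
      std::vector<int> &vf = m.vfaces[v1];
      size_t w = 0;
      for (size_t r = 0; r < vf.size(); ++r)
        if (m.falive[vf[r]]) vf[w++] = vf[r];
      vf.resize(w);
    }
    m.vfaces[v2].clear();
    m.valive[v2] = 0;
    m.gen[v1]++;
    (void)old1; (void)old2;

    m.neighbors(v1, nb1);
    for (int u : nb1) push_edge(v1, u);
  }

  // compact
  std::vector<int> vmap(nv, -1);
  int nvo = 0;
  for (int v = 0; v < nv; ++v) if (m.valive[v]) vmap[v] = nvo++;
  int nfo = 0;
  for (int f = 0; f < nf; ++f) if (m.falive[f]) ++nfo;
  NumericMatrix Vo(nvo, 3);
  IntegerMatrix Fo(nfo, 3);
  for (int v = 0; v < nv; ++v)
    if (m.valive[v])
      for (int cc = 0; cc < 3; ++cc) Vo(vmap[v], cc) = m.V[3*v+cc];
  int fi = 0;
  for (int f = 0; f < nf; ++f) {
    if (!m.falive[f]) continue;
    for (int cc = 0; cc < 3; ++cc) Fo(fi, cc) = vmap[m.F[3*f+cc]] + 1;
    ++fi;
  }
  return List::create(_["vertices"] = Vo, _["faces"] = Fo);
}
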