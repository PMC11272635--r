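// Triangle-mesh collision detection: uniform-grid broadphase over a static
// mesh (the pelvis) plus Moller-style triangle-triangle intersection tests
// against a moving mesh (the posed femur). Intersection segments are
// returned so contact centroids can be computed on the static surface.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

struct Vec3 {
  double x, y, z;
};
static inline Vec3 v3(double x, double y, double z) { Vec3 v{x, y, z}; return v; }
static inline Vec3 sub(const Vec3& a, const Vec3& b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline Vec3 add(const Vec3& a, const Vec3& b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline Vec3 scale(const Vec3& a, double s) { return v3(a.x * s, a.y * s, a.z * s); }
static inline double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}

// Intersection points of a triangle with the plane of the other triangle,
// given the three signed distances. Writes the two crossing points.
static bool plane_crossings(const Vec3 t[3], const double d[3], Vec3 out[2]) {
  int n = 0;
  for (int i = 0; i < 3 && n < 2; ++i) {
    int j = (i + 1) % 3;
    if ((d[i] > 0 && d[j] < 0) || (d[i] < 0 && d[j] > 0)) {
      double f = d[i] / (d[i] - d[j]);
      out[n++] = add(t[i], scale(sub(t[j], t[i]), f));
    } else if (d[i] == 0 && n < 2) {
      out[n++] = t[i];
    }
  }
  return n == 2;
}

// Triangle-triangle intersection; on hit, fills the endpoints of the
// intersection segment. Coplanar contacts are ignored (measure-zero for the
// sweep searches this backs).
static bool tri_tri_segment(const Vec3 T1[3], const Vec3 T2[3], Vec3 seg[2]) {
  Vec3 N2 = cross(sub(T2[1], T2[0]), sub(T2[2], T2[0]));
  double d1[3], d2[3];
  for (int i = 0; i < 3; ++i) d1[i] = dot(N2, sub(T1[i], T2[0]));
  if ((d1[0] > 0 && d1[1] > 0 && d1[2] > 0) ||
      (d1[0] < 0 && d1[1] < 0 && d1[2] < 0)) return false;
  Vec3 N1 = cross(sub(T1[1], T1[0]), sub(T1[2], T1[0]));
  for (int i = 0; i < 3; ++i) d2[i] = dot(N1, sub(T2[i], T1[0]));
  if ((d2[0] > 0 && d2[1] > 0 && d2[2] > 0) ||
      (d2[0] < 0 && d2[1] < 0 && d2[2] < 0)) return false;
  Vec3 D = cross(N1, N2);
  double dn = std::sqrt(dot(D, D));
  if (dn < 1e-12) return false;               // coplanar or degenerate
  D = scale(D, 1.0 / dn);
  Vec3 a[2], b[2];
  if (!plane_crossings(T1, d1, a)) return false;
  if (!plane_crossings(T2, d2, b)) return false;
  double ta0 = dot(a[0], D), ta1 = dot(a[1], D);
  double tb0 = dot(b[0], D), tb1 = dot(b[1], D);
  if (ta0 > ta1) { std::swap(ta0, ta1); std::swap(a[0], a[1]); }
  if (tb0 > tb1) { std::swap(tb0, tb1); std::swap(b[0], b[1]); }
  double lo = std::max(ta0, tb0), hi = std::min(ta1, tb1);
  if (lo >= hi) return false;
  seg[0] = add(a[0], scale(D, lo - ta0));
  seg[1] = add(a[0], scale(D, hi - ta0));
  return true;
}

struct StaticMesh {
  std::vector<Vec3> tri;           // 3 verts per face, flattened
  std::vector<double> bb;          // per-face AABB (6 doubles)
  int nf;
  double gmin[3], gmax[3], h;
  int nx, ny, nz;
  std::vector<std::vector<int> > cells;
  std::vector<int> stamp;                // dedupe marker, see qid
  int qid;

  inline int cell_of(int ix, int iy, int iz) const {
    return (iz * ny + iy) * nx + ix;
  }
};

// [[Rcpp::export]]
SEXP cpp_collision_prepare(NumericMatrix V, IntegerMatrix F) {
  StaticMesh* m = new StaticMesh();
  int nf = F.nrow();
  m->nf = nf;
  m->tri.resize(3 * nf);
  m->bb.resize(6 * nf);
  double mn[3] = {1e30, 1e30, 1e30}, mx[3] = {-1e30, -1e30, -1e30};
  double mean_size = 0;
  for (int f = 0; f < nf; ++f) {
    for (int k = 0; k < 3; ++k) {
      int vi = F(f, k) - 1;
      m->tri[3 * f + k] = v3(V(vi, 0), V(vi, 1), V(vi, 2));
    }
    const Vec3* t = &m->tri[3 * f];
    double fb[6];
    for (int c = 0; c < 3; ++c) {
      double lo = std::min(std::min((&t[0].x)[c], (&t[1].x)[c]), (&t[2].x)[c]);
      double hi = std::max(std::max((&t[0].x)[c], (&t[1].x)[c]), (&t[2].x)[c]);
      fb[c] = lo; fb[3 + c] = hi;
      mn[c] = std::min(mn[c], lo); mx[c] = std::max(mx[c], hi);
      mean_size += (hi - lo);
    }
    for (int c = 0; c < 6; ++c) m->bb[6 * f + c] = fb[c];
  }
  mean_size /= (3.0 * nf);
  double h = std::max(0.5, 1.5 * mean_size);
  for (int c = 0; c < 3; ++c) { m->gmin[c] = mn[c] - 1e-6; m->gmax[c] = mx[c] + 1e-6; }
  m->nx = std::min(192, std::max(1, (int)std::ceil((m->gmax[0] - m->gmin[0]) / h)));
  m->ny = std::min(192, std::max(1, (int)std::ceil((m->gmax[1] - m->gmin[1]) / h)));
  m->nz = std::min(192, std::max(1, (int)std::ceil((m->gmax[2] - m->gmin[2]) / h)));
  m->h = h;
  m->cells.resize((size_t)m->nx * m->ny * m->nz);
  for (int f = 0; f < nf; ++f) {
    const double* fb = &m->bb[6 * f];
    int i0[3], i1[3];
    for (int c = 0; c < 3; ++c) {
      double span = m->gmax[c] - m->gmin[c];
      int n = (c == 0 ? m->nx : (c == 1 ? m->ny : m->nz));
      i0[c] = std::max(0, std::min(n - 1, (int)((fb[c] - m->gmin[c]) / span * n)));
      i1[c] = std::max(0, std::min(n - 1, (int)((fb[3 + c] - m->gmin[c]) / span * n)));
    }
    for (int iz = i0[2]; iz <= i1[2]; ++iz)
      for (int iy = i0[1]; iy <= i1[1]; ++iy)
        for (int ix = i0[0]; ix <= i1[0]; ++ix)
          m->cells[m->cell_of(ix, iy, iz)].push_back(f);
  }
  m->stamp.assign(nf, -1);
  m->qid = 0;
  XPtr<StaticMesh> p(m, true);
  return p;
}

// Collide a moving mesh against the prepared static mesh. If first_only,
// returns as soon as any intersection is found.
// [[Rcpp::export]]
List cpp_collide(SEXP prep, NumericMatrix V, IntegerMatrix F, bool first_only) {
  XPtr<StaticMesh> m(prep);
  if (m->qid > 2000000000) { m->stamp.assign(m->nf, -1); m->qid = 0; }
  int nf = F.nrow();
  std::vector<int> pair_s, pair_m;
  std::vector<double> segs;
  Vec3 T2[3], seg[2];
  for (int f = 0; f < nf; ++f) {
    for (int k = 0; k < 3; ++k) {
      int vi = F(f, k) - 1;
      T2[k] = v3(V(vi, 0), V(vi, 1), V(vi, 2));
    }
    double fb[6];
    for (int c = 0; c < 3; ++c) {
      double lo = std::min(std::min((&T2[0].x)[c], (&T2[1].x)[c]), (&T2[2].x)[c]);
      double hi = std::max(std::max((&T2[0].x)[c], (&T2[1].x)[c]), (&T2[2].x)[c]);
      fb[c] = lo; fb[3 + c] = hi;
    }
    bool out = false;
    for (int c = 0; c < 3; ++c)
      if (fb[3 + c] < m->gmin[c] || fb[c] > m->gmax[c]) { out = true; break; }
    if (out) continue;
    int i0[3], i1[3];
    for (int c = 0; c < 3; ++c) {
      double span = m->gmax[c] - m->gmin[c];
      int n = (c == 0 ? m->nx : (c == 1 ? m->ny : m->nz));
      i0[c] = std::max(0, std::min(n - 1, (int)((fb[c] - m->gmin[c]) / span * n)));
      i1[c] = std::max(0, std::min(n - 1, (int)((fb[3 + c] - m->gmin[c]) / span * n)));
    }
    ++m->qid;
    for (int iz = i0[2]; iz <= i1[2]; ++iz)
      for (int iy = i0[1]; iy <= i1[1]; ++iy)
        for (int ix = i0[0]; ix <= i1[0]; ++ix) {
          const std::vector<int>& cell = m->cells[m->cell_of(ix, iy, iz)];
          for (size_t ci = 0; ci < cell.size(); ++ci) {
            int sf = cell[ci];
            if (m->stamp[sf] == m->qid) continue;
            m->stamp[sf] = m->qid;
            const double* sb = &m->bb[6 * sf];
            bool sep = false;
            for (int c = 0; c < 3; ++c)
              if (fb[3 + c] < sb[c] || fb[c] > sb[3 + c]) { sep = true; break; }
            if (sep) continue;
            if (tri_tri_segment(&m->tri[3 * sf], T2, seg)) {
              pair_s.push_back(sf + 1);
              pair_m.push_back(f + 1);
              segs.push_back(seg[0].x); segs.push_back(seg[0].y); segs.push_back(seg[0].z);
              segs.push_back(seg[1].x); segs.push_back(seg[1].y); segs.push_back(seg[1].z);
              if (first_only)
                return List::create(_["hit"] = true,
                                    _["pairs"] = IntegerMatrix(0, 2),
                                    _["segments"] = NumericMatrix(0, 6));
            }
          }
        }
  }
  int k = pair_s.size();
  IntegerMatrix pairs(k, 2);
  NumericMatrix sm(k, 6);
  for (int i = 0; i < k; ++i) {
    pairs(i, 0) = pair_s[i];
    pairs(i, 1) = pair_m[i];
    for (int c = 0; c < 6; ++c) sm(i, c) = segs[6 * i + c];
  }
  return List::create(_["hit"] = (k > 0), _["pairs"] = pairs, _["segments"] = sm);
}
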