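// Incremental Bowyer-Watson 3-D Delaunay tetrahedralization.
// Points are expected pre-scaled to roughly the unit box and symbolically
// jittered by the caller; predicates are plain doubles with relative
// tolerances, which the jitter keeps away from degeneracy.
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Tet {
  int v[4];        // vertex indices
  int n[4];        // n[k]: neighbour sharing the face opposite v[k], -1 if none
  double cc[3];    // circumcentre
  double r2;       // squared circumradius
  bool alive;
};

struct Mesh3 {
  std::vector<std::array<double,3>> pts;
  std::vector<Tet> tets;
};

inline double orient3d(const double* a, const double* b,
                       const double* c, const double* d) {
  double adx = a[0]-d[0], ady = a[1]-d[1], adz = a[2]-d[2];
  double bdx = b[0]-d[0], bdy = b[1]-d[1], bdz = b[2]-d[2];
  double cdx = c[0]-d[0], cdy = c[1]-d[1], cdz = c[2]-d[2];
  return adx*(bdy*cdz - bdz*cdy) - ady*(bdx*cdz - bdz*cdx)
       + adz*(bdx*cdy - bdy*cdx);
}

// Circumsphere from the linear system 2(b-a).x = |b|^2-|a|^2 etc.
inline void circumsphere(const double* a, const double* b,
                         const double* c, const double* d,
                         double* cc, double& r2) {
  double m[3][3], rhs[3];
  const double* q[3] = {b, c, d};
  for (int i = 0; i < 3; ++i) {
    rhs[i] = 0.0;
    for (int j = 0; j < 3; ++j) {
      m[i][j] = 2.0*(q[i][j] - a[j]);
      rhs[i] += q[i][j]*q[i][j] - a[j]*a[j];
    }
  }
  // Cramer
  double det =
      m[0][0]*(m[1][1]*m[2][2]-m[1][2]*m[2][1])
    - m[0][1]*(m[1][0]*m[2][2]-m[1][2]*m[2][0])
    + m[0][2]*(m[1][0]*m[2][1]-m[1][1]*m[2][0]);
  if (std::fabs(det) < 1e-300) {             // flat tet: infinite sphere
    cc[0] = cc[1] = cc[2] = 0.0;
    r2 = std::numeric_limits<double>::infinity();
    return;
  }
  double x[3];
  for (int k = 0; k < 3; ++k) {
    double t[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) t[i][j] = (j == k) ? rhs[i] : m[i][j];
    double dk =
        t[0][0]*(t[1][1]*t[2][2]-t[1][2]*t[2][1])
      - t[0][1]*(t[1][0]*t[2][2]-t[1][2]*t[2][0])
      + t[0][2]*(t[1][0]*t[2][1]-t[1][1]*t[2][0]);
    x[k] = dk/det;
  }
  cc[0] = x[0]; cc[1] = x[1]; cc[2] = x[2];
  double dx = a[0]-x[0], dy = a[1]-x[1], dz = a[2]-x[2];
  r2 = dx*dx + dy*dy + dz*dz;
}

inline const double* P(const Mesh3& M, int i) { return M.pts[(size_t)i].data(); }

// determinant insphere test for a positively oriented tet; > 0 inside.
// A floating-point filter (sum of absolute expansion terms) guards the
// sign; ties within the error band count as outside and are resolved by
// the caller's symbolic jitter.
inline bool in_sphere(const Mesh3& M, const Tet& t, const double* p) {
  double m[4][4];
  for (int i = 0; i < 4; ++i) {
    const double* v = P(M, t.v[i]);
    double dx = v[0]-p[0], dy = v[1]-p[1], dz = v[2]-p[2];
    m[i][0] = dx; m[i][1] = dy; m[i][2] = dz;
    m[i][3] = dx*dx + dy*dy + dz*dz;
  }
  auto det3 = [&](int r0, int r1, int r2) {
    return m[r0][0]*(m[r1][1]*m[r2][2]-m[r1][2]*m[r2][1])
         - m[r0][1]*(m[r1][0]*m[r2][2]-m[r1][2]*m[r2][0])
         + m[r0][2]*(m[r1][0]*m[r2][1]-m[r1][1]*m[r2][0]);
  };
  auto det3abs = [&](int r0, int r1, int r2) {
    return std::fabs(m[r0][0])*(std::fabs(m[r1][1]*m[r2][2])+std::fabs(m[r1][2]*m[r2][1]))
         + std::fabs(m[r0][1])*(std::fabs(m[r1][0]*m[r2][2])+std::fabs(m[r1][2]*m[r2][0]))
         + std::fabs(m[r0][2])*(std::fabs(m[r1][0]*m[r2][1])+std::fabs(m[r1][1]*m[r2][0]));
  };
  double det = -m[0][3]*det3(1,2,3) + m[1][3]*det3(0,2,3)
             - m[2][3]*det3(0,1,3) + m[3][3]*det3(0,1,2);
  double mag = std::fabs(m[0][3])*det3abs(1,2,3) + std::fabs(m[1][3])*det3abs(0,2,3)
             + std::fabs(m[2][3])*det3abs(0,1,3) + std::fabs(m[3][3])*det3abs(0,1,2);
  return det > 1e-12 * mag;
}

int make_tet(Mesh3& M, int a, int b, int c, int d) {
  Tet t;
  if (orient3d(P(M,a), P(M,b), P(M,c), P(M,d)) < 0) std::swap(c, d);
  t.v[0]=a; t.v[1]=b; t.v[2]=c; t.v[3]=d;
  t.n[0]=t.n[1]=t.n[2]=t.n[3]=-1;
  circumsphere(P(M,a), P(M,b), P(M,c), P(M,d), t.cc, t.r2);
  t.alive = true;
  M.tets.push_back(t);
  return (int)M.tets.size() - 1;
}

// walk from tet `start` towards point p; returns a tet whose circumsphere
// contains p, or -1
int locate(const Mesh3& M, int start, const double* p) {
  int cur = start, steps = 0, limit = (int)M.tets.size() + 64;
  while (cur >= 0 && steps++ < limit) {
    const Tet& t = M.tets[(size_t)cur];
    if (!t.alive) break;
    if (in_sphere(M, t, p)) return cur;
    // move through the face p is most outside of
    int best = -1; double worst = -1e-13;
    for (int k = 0; k < 4; ++k) {
      // face opposite v[k]; p outside if on the other side from v[k]
      int f0 = t.v[(k+1)&3], f1 = t.v[(k+2)&3], f2 = t.v[(k+3)&3];
      double sv = orient3d(P(M,f0), P(M,f1), P(M,f2), P(M,t.v[k]));
      double sp = orient3d(P(M,f0), P(M,f1), P(M,f2), p);
      double side = (sv > 0 ? -sp : sp);   // >0 when p beyond this face
      if (side > worst) { worst = side; best = k; }
    }
    if (best < 0 || worst <= 0) break;     // p inside but sphere test failed
    cur = t.n[best];
  }
  // fallback: linear scan
  for (size_t i = M.tets.size(); i-- > 0; )
    if (M.tets[i].alive && in_sphere(M, M.tets[i], p)) return (int)i;
  return -1;
}

} // namespace

// [[Rcpp::export(name = ".delaunay3d_cpp")]]
List delaunay3d_cpp(NumericMatrix points) {
  const int n = points.nrow();
  if (n < 4) stop("Delaunay tetrahedralization needs at least 4 points");
  Mesh3 M;
  M.pts.resize((size_t)n + 4);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) {
      double v = points(i, j);
      M.pts[(size_t)i][(size_t)j] = v;
      if (v < lo[j]) lo[j] = v;
      if (v > hi[j]) hi[j] = v;
    }
  double cx = 0.5*(lo[0]+hi[0]), cy = 0.5*(lo[1]+hi[1]), cz = 0.5*(lo[2]+hi[2]);
  double span = std::max({hi[0]-lo[0], hi[1]-lo[1], hi[2]-lo[2], 1e-8});
  double R = 2000.0 * span;
  // super-tetrahedron
  M.pts[(size_t)n+0] = {cx - R,       cy - R,       cz - R};
  M.pts[(size_t)n+1] = {cx + 3.0*R,   cy - R,       cz - R};
  M.pts[(size_t)n+2] = {cx,           cy + 3.0*R,   cz - R};
  M.pts[(size_t)n+3] = {cx,           cy,           cz + 3.0*R};
  M.tets.reserve((size_t)12*n + 16);
  int last = make_tet(M, n, n+1, n+2, n+3);

  std::vector<int> cavity, bfaces;           // bfaces: outside tet + 3 verts
  std::vector<char> inCav;
  std::vector<int> stack;

  for (int ip = 0; ip < n; ++ip) {
    const double* p = P(M, ip);
    int seed = locate(M, last, p);
    if (seed < 0)
      stop("point location failed during tetrahedralization (degenerate input?)");
    // grow cavity
    cavity.clear(); bfaces.clear(); stack.clear();
    if (inCav.size() < M.tets.size()) inCav.resize(M.tets.size() + 1024, 0);
    stack.push_back(seed); inCav[(size_t)seed] = 1;
    while (!stack.empty()) {
      int ti = stack.back(); stack.pop_back();
      cavity.push_back(ti);
      const Tet& t = M.tets[(size_t)ti];
      for (int k = 0; k < 4; ++k) {
        int nb = t.n[k];
        if (nb >= 0 && !inCav[(size_t)nb] && M.tets[(size_t)nb].alive &&
            in_sphere(M, M.tets[(size_t)nb], p)) {
          inCav[(size_t)nb] = 1;
          stack.push_back(nb);
        }
      }
    }
    // boundary faces of the cavity
    for (int ti : cavity) {
      const Tet& t = M.tets[(size_t)ti];
      for (int k = 0; k < 4; ++k) {
        int nb = t.n[k];
        if (nb < 0 || !inCav[(size_t)nb]) {
          bfaces.push_back(nb);
          bfaces.push_back(t.v[(k+1)&3]);
          bfaces.push_back(t.v[(k+2)&3]);
          bfaces.push_back(t.v[(k+3)&3]);
        }
      }
    }
    for (int ti : cavity) { M.tets[(size_t)ti].alive = false; inCav[(size_t)ti] = 0; }
    // retriangulate: one tet per boundary face, linked via shared edges
    std::unordered_map<std::uint64_t, std::pair<int,int>> edgeMap;
    edgeMap.reserve(bfaces.size());
    int nV = (int)M.pts.size();
    int firstNew = -1;
    for (size_t f = 0; f < bfaces.size(); f += 4) {
      int outside = bfaces[f];
      int a = bfaces[f+1], b = bfaces[f+2], c = bfaces[f+3];
      int nt = make_tet(M, ip, a, b, c);
      if (firstNew < 0) firstNew = nt;
      if ((size_t)nt >= inCav.size()) inCav.resize((size_t)nt + 1024, 0);
      Tet& T = M.tets[(size_t)nt];
      // neighbour across the base face (the one not containing ip)
      for (int k = 0; k < 4; ++k)
        if (T.v[k] == ip) { T.n[k] = outside; break; }
      if (outside >= 0) {
        Tet& O = M.tets[(size_t)outside];
        // O's face shared with T is the one opposite the vertex of O that
        // is not in {a,b,c}
        for (int k = 0; k < 4; ++k) {
          int w = O.v[k];
          if (w != a && w != b && w != c) { O.n[k] = nt; break; }
        }
      }
      // link across the three edges of the base face (faces containing ip)
      int e[3][2] = {{a,b},{b,c},{c,a}};
      for (int k = 0; k < 3; ++k) {
        int u = e[k][0], v = e[k][1];
        std::uint64_t key = (std::uint64_t)std::min(u,v) * (std::uint64_t)nV
                          + (std::uint64_t)std::max(u,v);
        auto it = edgeMap.find(key);
        if (it == edgeMap.end()) {
          edgeMap[key] = {nt, u ^ v};        // remember tet; opposite via xor
        } else {
          int other = it->second.first;
          // in T, shared face = {ip,u,v}: opposite vertex is the base vertex
          // not in {u,v}; same logic for `other`
          Tet& A = M.tets[(size_t)nt];
          Tet& B = M.tets[(size_t)other];
          for (int k2 = 0; k2 < 4; ++k2) {
            int w = A.v[k2];
            if (w != ip && w != u && w != v) { A.n[k2] = other; break; }
          }
          for (int k2 = 0; k2 < 4; ++k2) {
            int w = B.v[k2];
            if (w != ip && w != u && w != v) { B.n[k2] = nt; break; }
          }
          edgeMap.erase(it);
        }
      }
    }
    last = firstNew;
    if ((ip & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  // collect real tets
  std::vector<int> keep;
  keep.reserve(M.tets.size());
  for (size_t i = 0; i < M.tets.size(); ++i) {
    const Tet& t = M.tets[i];
    if (!t.alive) continue;
    if (t.v[0] >= n || t.v[1] >= n || t.v[2] >= n || t.v[3] >= n) continue;
    keep.push_back((int)i);
  }
  std::vector<int> newid(M.tets.size(), -1);
  for (size_t k = 0; k < keep.size(); ++k) newid[(size_t)keep[k]] = (int)k;
  int m = (int)keep.size();
  IntegerMatrix tets(m, 4), nbrs(m, 4);
  NumericVector radius(m);
  for (int k = 0; k < m; ++k) {
    const Tet& t = M.tets[(size_t)keep[k]];
    for (int j = 0; j < 4; ++j) {
      tets(k, j) = t.v[j] + 1;                       // 1-based for R
      int nb = t.n[j];
      nbrs(k, j) = (nb >= 0 && newid[(size_t)nb] >= 0) ? newid[(size_t)nb] + 1
                                                       : NA_INTEGER;
    }
    radius[k] = std::sqrt(t.r2);
  }
  return List::create(_["tets"] = tets, _["neighbors"] = nbrs,
                      _["circumradius"] = radius);
}
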