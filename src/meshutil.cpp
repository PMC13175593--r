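// Mesh connectivity helpers: consistent face orientation by propagation
// across manifold edges, and undirected-edge incidence counting.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline std::uint64_t ekey(int u, int v, int nV) {
  int a = u < v ? u : v, b = u < v ? v : u;
  return (std::uint64_t)a * (std::uint64_t)nV + (std::uint64_t)b;
}

// Reorients faces so adjacent faces traverse shared manifold edges in
// opposite directions. Returns the reoriented face matrix; orientation
// within each connected component is consistent up to a global flip.
// [[Rcpp::export(name = ".orient_faces_cpp")]]
IntegerMatrix orient_faces_cpp(IntegerMatrix faces, int nV) {
  const int m = faces.nrow();
  std::vector<std::array<int,3>> F((size_t)m);
  for (int f = 0; f < m; ++f)
    F[(size_t)f] = {faces(f,0)-1, faces(f,1)-1, faces(f,2)-1};
  std::unordered_map<std::uint64_t, std::vector<int>> inc;
  inc.reserve((size_t)m*2);
  for (int f = 0; f < m; ++f)
    for (int k = 0; k < 3; ++k)
      inc[ekey(F[(size_t)f][(size_t)k], F[(size_t)f][(size_t)((k+1)%3)], nV)].push_back(f);
  std::vector<char> seen((size_t)m, 0);
  std::vector<int> stack;
  for (int root = 0; root < m; ++root) {
    if (seen[(size_t)root]) continue;
    seen[(size_t)root] = 1;
    stack.push_back(root);
    while (!stack.empty()) {
      int f = stack.back(); stack.pop_back();
      for (int k = 0; k < 3; ++k) {
        int u = F[(size_t)f][(size_t)k], v = F[(size_t)f][(size_t)((k+1)%3)];
        auto& fl = inc[ekey(u, v, nV)];
        if (fl.size() != 2) continue;            // boundary or non-manifold
        int g = fl[0] == f ? fl[1] : fl[0];
        if (seen[(size_t)g]) continue;
        // g must traverse edge as (v,u); if it has (u,v), flip g
        bool same = false;
        for (int j = 0; j < 3; ++j) {
          if (F[(size_t)g][(size_t)j] == u &&
              F[(size_t)g][(size_t)((j+1)%3)] == v) { same = true; break; }
        }
        if (same) std::swap(F[(size_t)g][1], F[(size_t)g][2]);
        seen[(size_t)g] = 1;
        stack.push_back(g);
      }
    }
  }
  IntegerMatrix out(m, 3);
  for (int f = 0; f < m; ++f)
    for (int k = 0; k < 3; ++k) out(f, k) = F[(size_t)f][(size_t)k] + 1;
  return out;
}

// per-edge face counts; returns matrix [u, v, count] with 1-based u < v
// [[Rcpp::export(name = ".edge_face_count_cpp")]]
IntegerMatrix edge_face_count_cpp(IntegerMatrix faces, int nV) {
  const int m = faces.nrow();
  std::unordered_map<std::uint64_t, int> cnt;
  cnt.reserve((size_t)m*2);
  for (int f = 0; f < m; ++f)
    for (int k = 0; k < 3; ++k)
      cnt[ekey(faces(f,k)-1, faces(f,(k+1)%3)-1, nV)]++;
  IntegerMatrix out((int)cnt.size(), 3);
  int i = 0;
  for (auto& kv : cnt) {
    out(i,0) = (int)(kv.first / (std::uint64_t)nV) + 1;
    out(i,1) = (int)(kv.first % (std::uint64_t)nV) + 1;
    out(i,2) = kv.second;
    ++i;
  }
  return out;
}
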