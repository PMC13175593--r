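// Dense 3-D voxel utilities: separable Gaussian smoothing, connected-component
// labelling (6/18/26), boundary-voxel extraction and trilinear sampling.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".gaussian_blur3d_cpp")]]
NumericVector gaussian_blur3d_cpp(NumericVector vol, IntegerVector dim,
                                  NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  const int stride[3] = {1, nx, nx*ny};
  const int len[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(4.0*s);
    std::vector<double> k(2*r + 1);
    double sum = 0.0;
    for (int i = -r; i <= r; ++i) {
      k[(size_t)(i+r)] = std::exp(-0.5*i*i/(s*s));
      sum += k[(size_t)(i+r)];
    }
    for (double& v : k) v /= sum;
    const int n = len[ax], st = stride[ax];
    const int nLines = nx*ny*nz / n;
    // iterate over all lines along axis ax
    for (int line = 0; line < nLines; ++line) {
      // compute base index of this line
      int idx = line, base = 0;
      for (int d = 0; d < 3; ++d) {
        if (d == ax) continue;
        int l = len[d];
        base += (idx % l) * stride[d];
        idx /= l;
      }
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int j = -r; j <= r; ++j) {
          int q = i + j;
          if (q < 0) q = 0; else if (q >= n) q = n - 1;   // replicate edge
          acc += k[(size_t)(j+r)] * a[(size_t)(base + q*st)];
        }
        b[(size_t)(base + i*st)] = acc;
      }
    }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx*ny*nz;
  IntegerVector lab(n, 0);
  // neighbour offsets
  std::vector<std::array<int,3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off.push_back({dx, dy, dz});
      }
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int x = (int)(cur % nx), y = (int)((cur / nx) % ny), z = (int)(cur / ((R_xlen_t)nx*ny));
      for (auto& o : off) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        R_xlen_t q = (R_xlen_t)xx + (R_xlen_t)nx*(yy + (R_xlen_t)ny*zz);
        if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// true voxels with at least one false 6-neighbour (out of bounds counts false)
// [[Rcpp::export(name = ".boundary_voxels_cpp")]]
IntegerMatrix boundary_voxels_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> xs, ys, zs;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = (R_xlen_t)x + (R_xlen_t)nx*(y + (R_xlen_t)ny*z);
        if (!mask[i]) continue;
        bool bnd =
          x == 0 || !mask[i-1] || x == nx-1 || !mask[i+1] ||
          y == 0 || !mask[i-nx] || y == ny-1 || !mask[i+nx] ||
          z == 0 || !mask[i-(R_xlen_t)nx*ny] || z == nz-1 || !mask[i+(R_xlen_t)nx*ny];
        if (bnd) { xs.push_back(x); ys.push_back(y); zs.push_back(z); }
      }
  IntegerMatrix out((int)xs.size(), 3);
  for (size_t k = 0; k < xs.size(); ++k) {
    out((int)k, 0) = xs[k]; out((int)k, 1) = ys[k]; out((int)k, 2) = zs[k];
  }
  return out;
}

// trilinear sampling at continuous 0-based voxel coordinates; outside -> fill
// [[Rcpp::export(name = ".trilinear_cpp")]]
NumericVector trilinear_cpp(NumericVector vol, IntegerVector dim,
                            NumericMatrix coords, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = coords.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double x = coords(i,0), y = coords(i,1), z = coords(i,2);
    if (!(x >= 0 && x <= nx-1 && y >= 0 && y <= ny-1 && z >= 0 && z <= nz-1)) {
      out[i] = fill;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == nx-1) x0--; if (y0 == ny-1) y0--; if (z0 == nz-1) z0--;
    if (nx == 1) x0 = 0; if (ny == 1) y0 = 0; if (nz == 1) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    if (nx == 1) fx = 0; if (ny == 1) fy = 0; if (nz == 1) fz = 0;
    auto V = [&](int a, int b, int c) -> double {
      if (a >= nx) a = nx-1; if (b >= ny) b = ny-1; if (c >= nz) c = nz-1;
      return vol[(R_xlen_t)a + (R_xlen_t)nx*(b + (R_xlen_t)ny*c)];
    };
    double c00 = V(x0,y0,z0)*(1-fx) + V(x0+1,y0,z0)*fx;
    double c10 = V(x0,y0+1,z0)*(1-fx) + V(x0+1,y0+1,z0)*fx;
    double c01 = V(x0,y0,z0+1)*(1-fx) + V(x0+1,y0,z0+1)*fx;
    double c11 = V(x0,y0+1,z0+1)*(1-fx) + V(x0+1,y0+1,z0+1)*fx;
    double c0 = c00*(1-fy) + c10*fy;
    double c1 = c01*(1-fy) + c11*fy;
    out[i] = c0*(1-fz) + c1*fz;
  }
  return out;
}
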