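// Triangle rasterization into a square pixel grid with barycentric
// interpolation; overlapping coverage keeps the maximum value.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// pos: n x 2 vertex positions in pixel coordinates (0-based, pixel centres at
// integers); faces: m x 3 (1-based); values: per-vertex (length n) or
// per-face (length m, flat shading). Background = NaN.
// [[Rcpp::export(name = ".rasterize_cpp")]]
NumericMatrix rasterize_cpp(NumericMatrix pos, IntegerMatrix faces,
                            NumericVector values, int res, bool per_face) {
  NumericMatrix img(res, res);
  std::fill(img.begin(), img.end(), NA_REAL);
  const int m = faces.nrow();
  for (int f = 0; f < m; ++f) {
    int a = faces(f,0)-1, b = faces(f,1)-1, c = faces(f,2)-1;
    double ax = pos(a,0), ay = pos(a,1);
    double bx = pos(b,0), by = pos(b,1);
    double cx = pos(c,0), cy = pos(c,1);
    double den = (bx-ax)*(cy-ay) - (cx-ax)*(by-ay);
    if (std::fabs(den) < 1e-14) continue;
    int x0 = std::max(0, (int)std::floor(std::min({ax,bx,cx})));
    int x1 = std::min(res-1, (int)std::ceil(std::max({ax,bx,cx})));
    int y0 = std::max(0, (int)std::floor(std::min({ay,by,cy})));
    int y1 = std::min(res-1, (int)std::ceil(std::max({ay,by,cy})));
    double va = per_face ? values[f] : values[a];
    double vb = per_face ? values[f] : values[b];
    double vc = per_face ? values[f] : values[c];
    for (int y = y0; y <= y1; ++y) {
      for (int x = x0; x <= x1; ++x) {
        double l1 = ((bx-(double)x)*(cy-(double)y) - (cx-(double)x)*(by-(double)y)) / den;
        double l2 = ((cx-(double)x)*(ay-(double)y) - (ax-(double)x)*(cy-(double)y)) / den;
        double l3 = 1.0 - l1 - l2;
        if (l1 < -1e-9 || l2 < -1e-9 || l3 < -1e-9) continue;
        double v = l1*va + l2*vb + l3*vc;
        double cur = img(y, x);
        if (ISNAN(cur) || v > cur) img(y, x) = v;
      }
    }
  }
  return img;
}
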