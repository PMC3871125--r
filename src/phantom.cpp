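// Distance stamping for phantom vessels: given a densely sampled centerline,
// record for every pixel within `radius` the distance to the nearest sample
// and that sample's tangent angle.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

//' @noRd
// [[Rcpp::export(name = ".stamp_vessel_cpp")]]
List stamp_vessel_cpp(int nrow, int ncol, NumericVector xs, NumericVector ys,
                      NumericVector tang, double radius) {
  NumericMatrix dist(nrow, ncol), ang(nrow, ncol);
  std::fill(dist.begin(), dist.end(), R_PosInf);
  std::fill(ang.begin(), ang.end(), NA_REAL);
  int n = xs.size();
  for (int i = 0; i < n; ++i) {
    // xs, ys are 1-based pixel coordinates (x = column, y = row)
    double cx = xs[i] - 1.0, cy = ys[i] - 1.0;
    int r0 = std::max(0, (int)std::floor(cy - radius));
    int r1 = std::min(nrow - 1, (int)std::ceil(cy + radius));
    int c0 = std::max(0, (int)std::floor(cx - radius));
    int c1 = std::min(ncol - 1, (int)std::ceil(cx + radius));
    for (int r = r0; r <= r1; ++r) {
      for (int c = c0; c <= c1; ++c) {
        double dx = c - cx, dy = r - cy;
        double d = std::sqrt(dx * dx + dy * dy);
        if (d < dist(r, c)) {
          dist(r, c) = d;
          ang(r, c) = tang[i];
        }
      }
    }
  }
  return List::create(_["dist"] = dist, _["angle"] = ang);
}
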