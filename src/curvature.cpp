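// Difference-curvature enhancement and 8-direction orientation coding.
// Per pixel, the cross-sectional profile curvature
//   K = |P''| / (1 + P'^2)^(3/2)
// is evaluated in the 8 quantized directions theta_j = (j-1)*pi/8 using
// 3-point central differences at unit arc-length spacing (bilinear samples,
// reflected at the border).  Directions pair into orthogonal groups
// {j, j+4}; the signed curvature differences dK_j and their maximum D_max
// (>= 0 by sign-flip closure) form the enhancement map, and the arg-max j
// (smallest j on ties) is the orientation code.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

// reflect a continuous 0-based coordinate into [0, n-1]
double reflect_coord(double x, int n) {
  if (n == 1) return 0.0;
  double period = 2.0 * (n - 1);
  x -= std::floor(x / period) * period; // reduce into [0, period)
  return (x <= n - 1) ? x : period - x;
}

double bilin_reflect(const NumericMatrix &img, double x, double y) {
  // x: 0-based column, y: 0-based row
  int h = img.nrow(), w = img.ncol();
  x = reflect_coord(x, w);
  y = reflect_coord(y, h);
  int c0 = (int)std::floor(x), r0 = (int)std::floor(y);
  int c1 = std::min(c0 + 1, w - 1), r1 = std::min(r0 + 1, h - 1);
  double fx = x - c0, fy = y - r0;
  return (1 - fy) * ((1 - fx) * img(r0, c0) + fx * img(r0, c1)) +
         fy * ((1 - fx) * img(r1, c0) + fx * img(r1, c1));
}

inline double curv3(double pm, double p0, double pp) {
  double d1 = 0.5 * (pp - pm);
  double d2 = pp - 2.0 * p0 + pm;
  return std::fabs(d2) / std::pow(1.0 + d1 * d1, 1.5);
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".diff_curvature_cpp")]]
List diff_curvature_cpp(NumericMatrix img) {
  int h = img.nrow(), w = img.ncol();
  NumericMatrix dmax(h, w);
  IntegerMatrix code(h, w);
  double cs[8], sn[8];
  for (int j = 0; j < 8; ++j) {
    cs[j] = std::cos(j * M_PI / 8.0);
    sn[j] = std::sin(j * M_PI / 8.0);
  }
  for (int r = 0; r < h; ++r) {
    for (int c = 0; c < w; ++c) {
      double K[8];
      double p0 = img(r, c);
      for (int j = 0; j < 8; ++j) {
        double pm = bilin_reflect(img, c - cs[j], r - sn[j]);
        double pp = bilin_reflect(img, c + cs[j], r + sn[j]);
        K[j] = curv3(pm, p0, pp);
      }
      double best = -1e300;
      int bestj = 0;
      for (int j = 0; j < 8; ++j) {
        double dk = K[j] - K[(j + 4) % 8];
        if (dk > best) {
          best = dk;
          bestj = j;
        }
      }
      dmax(r, c) = best;
      code(r, c) = bestj + 1;
    }
  }
  return List::create(_["dmax"] = dmax, _["code"] = code);
}

//' @noRd
// [[Rcpp::export(name = ".profile_sample_cpp")]]
NumericVector profile_sample_cpp(NumericMatrix img, double x, double y,
                                 double angle, int r) {
  // x, y are 0-based; unit arc-length spacing along (cos angle, sin angle)
  NumericVector out(2 * r + 1);
  double dx = std::cos(angle), dy = std::sin(angle);
  for (int t = -r; t <= r; ++t)
    out[t + r] = bilin_reflect(img, x + t * dx, y + t * dy);
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".bilinear_sample_cpp")]]
NumericVector bilinear_sample_cpp(NumericMatrix img, NumericVector x,
                                  NumericVector y, int mode) {
  // mode 0: reflect, 1: clamp, 2: NA outside
  int h = img.nrow(), w = img.ncol(), n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i], yi = y[i];
    if (mode == 2 && (xi < 0 || xi > w - 1 || yi < 0 || yi > h - 1)) {
      out[i] = NA_REAL;
      continue;
    }
    if (mode == 1) {
      xi = std::min(std::max(xi, 0.0), (double)(w - 1));
      yi = std::min(std::max(yi, 0.0), (double)(h - 1));
    }
    out[i] = bilin_reflect(img, xi, yi);
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".nearest_sample_cpp")]]
NumericVector nearest_sample_cpp(NumericMatrix img, NumericVector x,
                                 NumericVector y, double fill) {
  int h = img.nrow(), w = img.ncol(), n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int c = (int)std::lround(x[i]), r = (int)std::lround(y[i]);
    out[i] = (c < 0 || c >= w || r < 0 || r >= h) ? fill : img(r, c);
  }
  return out;
}
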