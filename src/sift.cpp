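// Scale-invariant keypoint detection and 128-element descriptors on
// grayscale images: Gaussian scale-space pyramid, difference-of-Gaussian
// extrema with sub-pixel localization, edge rejection, gradient-orientation
// assignment and the standard 4x4x8 descriptor grid.  Fully deterministic.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Img {
  int h, w;
  std::vector<double> v;
  Img() : h(0), w(0) {}
  Img(int h_, int w_) : h(h_), w(w_), v(static_cast<size_t>(h_) * w_, 0.0) {}
  double &at(int r, int c) { return v[static_cast<size_t>(c) * h + r]; }
  double at(int r, int c) const { return v[static_cast<size_t>(c) * h + r]; }
};

int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : period - 1 - i;
}

// separable Gaussian blur, kernel truncated at 3 sigma, reflect boundary
Img gauss_blur(const Img &src, double sigma) {
  if (sigma <= 0) return src;
  int radius = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * radius + 1);
  double s = 0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + radius];
  }
  for (double &x : k) x /= s;
  Img tmp(src.h, src.w), out(src.h, src.w);
  for (int c = 0; c < src.w; ++c)
    for (int r = 0; r < src.h; ++r) {
      double acc = 0;
      for (int i = -radius; i <= radius; ++i)
        acc += k[i + radius] * src.at(reflect_idx(r + i, src.h), c);
      tmp.at(r, c) = acc;
    }
  for (int r = 0; r < src.h; ++r)
    for (int c = 0; c < src.w; ++c) {
      double acc = 0;
      for (int i = -radius; i <= radius; ++i)
        acc += k[i + radius] * tmp.at(r, reflect_idx(c + i, src.w));
      out.at(r, c) = acc;
    }
  return out;
}

Img upsample2(const Img &src) {
  Img out(src.h * 2, src.w * 2);
  for (int r = 0; r < out.h; ++r)
    for (int c = 0; c < out.w; ++c) {
      double y = r * 0.5, x = c * 0.5;
      int r0 = (int)y, c0 = (int)x;
      int r1 = std::min(r0 + 1, src.h - 1), c1 = std::min(c0 + 1, src.w - 1);
      double fy = y - r0, fx = x - c0;
      out.at(r, c) = (1 - fy) * ((1 - fx) * src.at(r0, c0) + fx * src.at(r0, c1)) +
                     fy * ((1 - fx) * src.at(r1, c0) + fx * src.at(r1, c1));
    }
  return out;
}

Img downsample2(const Img &src) {
  Img out(std::max(1, src.h / 2), std::max(1, src.w / 2));
  for (int r = 0; r < out.h; ++r)
    for (int c = 0; c < out.w; ++c)
      out.at(r, c) = src.at(std::min(r * 2, src.h - 1), std::min(c * 2, src.w - 1));
  return out;
}

struct Kpt {
  double x, y;      // base-pyramid coords (0-based)
  double scale;     // sigma relative to base image
  double angle;     // radians in [0, 2pi)
  int octave, layer;
  double xo, yo, scl_octv; // octave-relative position and sigma
  double response;
};

const double SIFT_SIGMA0 = 1.6;
const double SIFT_INIT_SIGMA = 0.5;
const int SIFT_MAX_INTERP = 5;
const int SIFT_BORDER = 5;
const int SIFT_ORI_BINS = 36;

bool interp_extremum(const std::vector<Img> &dog, int nlayers, int layer,
                     int r, int c, double contrast_thresh, double edge_thresh,
                     Kpt &kp) {
  double xi = 0, xr = 0, xc = 0, contr = 0;
  int i = 0;
  const Img *cur = nullptr, *lo = nullptr, *hi = nullptr;
  for (; i < SIFT_MAX_INTERP; ++i) {
    cur = &dog[layer]; lo = &dog[layer - 1]; hi = &dog[layer + 1];
    double dD[3] = {
      0.5 * (cur->at(r, c + 1) - cur->at(r, c - 1)),
      0.5 * (cur->at(r + 1, c) - cur->at(r - 1, c)),
      0.5 * (hi->at(r, c) - lo->at(r, c))
    };
    double v2 = 2.0 * cur->at(r, c);
    double dxx = cur->at(r, c + 1) + cur->at(r, c - 1) - v2;
    double dyy = cur->at(r + 1, c) + cur->at(r - 1, c) - v2;
    double dss = hi->at(r, c) + lo->at(r, c) - v2;
    double dxy = 0.25 * (cur->at(r + 1, c + 1) - cur->at(r + 1, c - 1) -
                         cur->at(r - 1, c + 1) + cur->at(r - 1, c - 1));
    double dxs = 0.25 * (hi->at(r, c + 1) - hi->at(r, c - 1) -
                         lo->at(r, c + 1) + lo->at(r, c - 1));
    double dys = 0.25 * (hi->at(r + 1, c) - hi->at(r - 1, c) -
                         lo->at(r + 1, c) + lo->at(r - 1, c));
    // solve H * x = -dD by Cramer's rule on the symmetric 3x3 Hessian
    double H[3][3] = {{dxx, dxy, dxs}, {dxy, dyy, dys}, {dxs, dys, dss}};
    double det = H[0][0] * (H[1][1] * H[2][2] - H[1][2] * H[2][1]) -
                 H[0][1] * (H[1][0] * H[2][2] - H[1][2] * H[2][0]) +
                 H[0][2] * (H[1][0] * H[2][1] - H[1][1] * H[2][0]);
    if (std::fabs(det) < 1e-12) return false;
    double b[3] = {-dD[0], -dD[1], -dD[2]};
    double x[3];
    for (int k = 0; k < 3; ++k) {
      double Hk[3][3];
      for (int a = 0; a < 3; ++a)
        for (int bcol = 0; bcol < 3; ++bcol)
          Hk[a][bcol] = (bcol == k) ? b[a] : H[a][bcol];
      double detk = Hk[0][0] * (Hk[1][1] * Hk[2][2] - Hk[1][2] * Hk[2][1]) -
                    Hk[0][1] * (Hk[1][0] * Hk[2][2] - Hk[1][2] * Hk[2][0]) +
                    Hk[0][2] * (Hk[1][0] * Hk[2][1] - Hk[1][1] * Hk[2][0]);
      x[k] = detk / det;
    }
    xc = x[0]; xr = x[1]; xi = x[2];
    if (std::fabs(xc) < 0.5 && std::fabs(xr) < 0.5 && std::fabs(xi) < 0.5) {
      contr = cur->at(r, c) + 0.5 * (dD[0] * xc + dD[1] * xr + dD[2] * xi);
      break;
    }
    c += (int)std::lround(xc);
    r += (int)std::lround(xr);
    layer += (int)std::lround(xi);
    if (layer < 1 || layer > nlayers ||
        r < SIFT_BORDER || r >= cur->h - SIFT_BORDER ||
        c < SIFT_BORDER || c >= cur->w - SIFT_BORDER)
      return false;
  }
  if (i >= SIFT_MAX_INTERP) return false;
  if (std::fabs(contr) * nlayers < contrast_thresh) return false;
  // principal-curvature (edge) test on the 2x2 spatial Hessian
  double v2 = 2.0 * cur->at(r, c);
  double dxx = cur->at(r, c + 1) + cur->at(r, c - 1) - v2;
  double dyy = cur->at(r + 1, c) + cur->at(r - 1, c) - v2;
  double dxy = 0.25 * (cur->at(r + 1, c + 1) - cur->at(r + 1, c - 1) -
                       cur->at(r - 1, c + 1) + cur->at(r - 1, c - 1));
  double tr = dxx + dyy, det2 = dxx * dyy - dxy * dxy;
  double er = edge_thresh;
  if (det2 <= 0 || tr * tr * er >= (er + 1) * (er + 1) * det2) return false;
  kp.layer = layer;
  kp.xo = c + xc;
  kp.yo = r + xr;
  kp.scl_octv = 0.0; // filled by caller (needs nlayers + layer + xi)
  kp.response = std::fabs(contr);
  kp.scale = layer + xi; // temporarily store interpolated layer
  return true;
}

// 36-bin gradient orientation histogram around (r,c); returns peak angles
void calc_orientations(const Img &g, double x, double y, double scl_octv,
                       std::vector<double> &angles) {
  int radius = (int)std::lround(3.0 * 1.5 * scl_octv);
  double sigma = 1.5 * scl_octv;
  double hist[SIFT_ORI_BINS] = {0};
  int rc = (int)std::lround(y), cc = (int)std::lround(x);
  for (int dr = -radius; dr <= radius; ++dr) {
    int r = rc + dr;
    if (r <= 0 || r >= g.h - 1) continue;
    for (int dc = -radius; dc <= radius; ++dc) {
      int c = cc + dc;
      if (c <= 0 || c >= g.w - 1) continue;
      double dx = 0.5 * (g.at(r, c + 1) - g.at(r, c - 1));
      double dy = 0.5 * (g.at(r + 1, c) - g.at(r - 1, c));
      double mag = std::sqrt(dx * dx + dy * dy);
      double ori = std::atan2(dy, dx);
      double wgt = std::exp(-(dr * dr + dc * dc) / (2.0 * sigma * sigma));
      int bin = (int)std::lround(SIFT_ORI_BINS * (ori + M_PI) / (2 * M_PI));
      bin = ((bin % SIFT_ORI_BINS) + SIFT_ORI_BINS) % SIFT_ORI_BINS;
      hist[bin] += wgt * mag;
    }
  }
  // circular smoothing with the [1 4 6 4 1]/16 kernel
  double sm[SIFT_ORI_BINS];
  for (int i = 0; i < SIFT_ORI_BINS; ++i) {
    int im2 = (i - 2 + SIFT_ORI_BINS) % SIFT_ORI_BINS;
    int im1 = (i - 1 + SIFT_ORI_BINS) % SIFT_ORI_BINS;
    int ip1 = (i + 1) % SIFT_ORI_BINS;
    int ip2 = (i + 2) % SIFT_ORI_BINS;
    sm[i] = (hist[im2] + hist[ip2]) * (1.0 / 16) +
            (hist[im1] + hist[ip1]) * (4.0 / 16) + hist[i] * (6.0 / 16);
  }
  double mx = *std::max_element(sm, sm + SIFT_ORI_BINS);
  if (mx <= 0) return;
  for (int i = 0; i < SIFT_ORI_BINS; ++i) {
    int l = (i - 1 + SIFT_ORI_BINS) % SIFT_ORI_BINS;
    int r2 = (i + 1) % SIFT_ORI_BINS;
    if (sm[i] > sm[l] && sm[i] > sm[r2] && sm[i] >= 0.8 * mx) {
      double bin = i + 0.5 * (sm[l] - sm[r2]) / (sm[l] - 2 * sm[i] + sm[r2]);
      bin = bin < 0 ? bin + SIFT_ORI_BINS : (bin >= SIFT_ORI_BINS ? bin - SIFT_ORI_BINS : bin);
      angles.push_back(2 * M_PI * bin / SIFT_ORI_BINS);
    }
  }
}

// standard 4x4 spatial x 8 orientation descriptor, trilinear interpolation
void calc_descriptor(const Img &g, double x, double y, double angle,
                     double scl_octv, double *dst) {
  const int d = 4, n = 8;
  double cos_t = std::cos(-angle), sin_t = std::sin(-angle);
  double bins_per_rad = n / (2 * M_PI);
  double exp_scale = -1.0 / (d * d * 0.5);
  double hist_width = 3.0 * scl_octv;
  int radius = (int)std::lround(hist_width * M_SQRT2 * (d + 1) * 0.5 + 0.5);
  radius = std::min(radius, (int)std::sqrt((double)g.h * g.h + (double)g.w * g.w));
  std::vector<double> hist((d + 2) * (d + 2) * (n + 2), 0.0);
  int rc = (int)std::lround(y), cc = (int)std::lround(x);
  for (int dr = -radius; dr <= radius; ++dr) {
    for (int dc = -radius; dc <= radius; ++dc) {
      double c_rot = (dc * cos_t - dr * sin_t) / hist_width;
      double r_rot = (dc * sin_t + dr * cos_t) / hist_width;
      double rbin = r_rot + d / 2 - 0.5, cbin = c_rot + d / 2 - 0.5;
      int r = rc + dr, c = cc + dc;
      if (rbin <= -1 || rbin >= d || cbin <= -1 || cbin >= d ||
          r <= 0 || r >= g.h - 1 || c <= 0 || c >= g.w - 1)
        continue;
      double dx = 0.5 * (g.at(r, c + 1) - g.at(r, c - 1));
      double dy = 0.5 * (g.at(r + 1, c) - g.at(r - 1, c));
      double mag = std::sqrt(dx * dx + dy * dy);
      double ori = std::atan2(dy, dx) + angle;
      double wgt = std::exp((c_rot * c_rot + r_rot * r_rot) * exp_scale);
      double obin = ori * bins_per_rad;
      double m = mag * wgt;
      int r0 = (int)std::floor(rbin), c0 = (int)std::floor(cbin);
      int o0 = (int)std::floor(obin);
      rbin -= r0; cbin -= c0; obin -= o0;
      o0 = ((o0 % n) + n) % n;
      // trilinear distribution into the (d+2)^2 x (n+2) histogram
      double v_r1 = m * rbin, v_r0 = m - v_r1;
      double v_rc11 = v_r1 * cbin, v_rc10 = v_r1 - v_rc11;
      double v_rc01 = v_r0 * cbin, v_rc00 = v_r0 - v_rc01;
      double v[4] = {v_rc00, v_rc01, v_rc10, v_rc11};
      for (int q = 0; q < 4; ++q) {
        int rr = r0 + 1 + (q >> 1), ccb = c0 + 1 + (q & 1);
        double v_o1 = v[q] * obin, v_o0 = v[q] - v_o1;
        size_t idx = ((size_t)rr * (d + 2) + ccb) * (n + 2) + o0;
        hist[idx] += v_o0;
        hist[idx + 1] += v_o1;
      }
    }
  }
  // fold the circular orientation bins and drop the spatial borders
  int k = 0;
  for (int r = 1; r <= d; ++r)
    for (int c = 1; c <= d; ++c) {
      size_t idx = ((size_t)r * (d + 2) + c) * (n + 2);
      hist[idx] += hist[idx + n];
      hist[idx + 1] += hist[idx + n + 1];
      for (int o = 0; o < n; ++o) dst[k++] = hist[idx + o];
    }
  double nrm = 0;
  for (int i = 0; i < d * d * n; ++i) nrm += dst[i] * dst[i];
  double thr = std::sqrt(nrm) * 0.2;
  nrm = 0;
  for (int i = 0; i < d * d * n; ++i) {
    if (dst[i] > thr) dst[i] = thr;
    nrm += dst[i] * dst[i];
  }
  nrm = 1.0 / std::max(std::sqrt(nrm), 1e-12);
  for (int i = 0; i < d * d * n; ++i) dst[i] *= nrm;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".sift_cpp")]]
List sift_cpp(NumericMatrix image, int n_layers = 3,
              double contrast_thresh = 0.04, double edge_thresh = 10.0,
              bool upsample = true, double sigma0 = 1.6) {
  int h = image.nrow(), w = image.ncol();
  Img base(h, w);
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r) base.at(r, c) = image(r, c);
  double init_sigma = SIFT_INIT_SIGMA;
  if (upsample) {
    base = upsample2(base);
    init_sigma *= 2.0;
  }
  double d2 = sigma0 * sigma0 - init_sigma * init_sigma;
  base = gauss_blur(base, d2 > 0 ? std::sqrt(d2) : 0.01);

  int min_dim = std::min(base.h, base.w);
  int n_oct = (int)std::floor(std::log2((double)min_dim)) - 2;
  if (n_oct < 1) n_oct = 1;

  double k = std::pow(2.0, 1.0 / n_layers);
  std::vector<double> sig(n_layers + 3);
  sig[0] = sigma0;
  for (int i = 1; i < n_layers + 3; ++i) {
    double prev = sigma0 * std::pow(k, i - 1);
    double total = prev * k;
    sig[i] = std::sqrt(total * total - prev * prev);
  }

  std::vector<Kpt> kps;
  std::vector<std::vector<Img>> gauss_pyr(n_oct);
  Img oct_base = base;
  for (int o = 0; o < n_oct; ++o) {
    std::vector<Img> &gp = gauss_pyr[o];
    gp.resize(n_layers + 3);
    gp[0] = oct_base;
    for (int i = 1; i < n_layers + 3; ++i) gp[i] = gauss_blur(gp[i - 1], sig[i]);
    std::vector<Img> dog(n_layers + 2);
    for (int i = 0; i < n_layers + 2; ++i) {
      dog[i] = Img(gp[i].h, gp[i].w);
      for (size_t t = 0; t < dog[i].v.size(); ++t)
        dog[i].v[t] = gp[i + 1].v[t] - gp[i].v[t];
    }
    double prelim = 0.5 * contrast_thresh / n_layers;
    for (int l = 1; l <= n_layers; ++l) {
      const Img &cur = dog[l], &lo = dog[l - 1], &hi = dog[l + 1];
      for (int r = SIFT_BORDER; r < cur.h - SIFT_BORDER; ++r)
        for (int c = SIFT_BORDER; c < cur.w - SIFT_BORDER; ++c) {
          double v = cur.at(r, c);
          if (std::fabs(v) <= prelim) continue;
          bool is_max = true, is_min = true;
          for (int dr = -1; dr <= 1 && (is_max || is_min); ++dr)
            for (int dc = -1; dc <= 1 && (is_max || is_min); ++dc) {
              for (const Img *im : {&lo, &cur, &hi}) {
                double nb = im->at(r + dr, c + dc);
                if (im == &cur && dr == 0 && dc == 0) continue;
                if (nb >= v) is_max = false;
                if (nb <= v) is_min = false;
              }
            }
          if (!is_max && !is_min) continue;
          Kpt kp;
          if (!interp_extremum(dog, n_layers, l, r, c, contrast_thresh,
                               edge_thresh, kp))
            continue;
          double interp_layer = kp.scale;
          kp.octave = o;
          kp.scl_octv = sigma0 * std::pow(2.0, interp_layer / n_layers);
          kp.x = kp.xo * std::pow(2.0, o);
          kp.y = kp.yo * std::pow(2.0, o);
          kp.scale = kp.scl_octv * std::pow(2.0, o);
          const Img &ori_img = gauss_pyr[o][kp.layer];
          std::vector<double> angles;
          calc_orientations(ori_img, kp.xo, kp.yo, kp.scl_octv, angles);
          for (double a : angles) {
            Kpt kp2 = kp;
            kp2.angle = a;
            kps.push_back(kp2);
          }
        }
    }
    if (o + 1 < n_oct) oct_base = downsample2(gp[n_layers]);
  }

  int nk = (int)kps.size();
  NumericMatrix out(nk, 5), desc(nk, 128);
  double coord_scale = upsample ? 0.5 : 1.0;
  std::vector<double> buf(128);
  for (int i = 0; i < nk; ++i) {
    const Kpt &kp = kps[i];
    calc_descriptor(gauss_pyr[kp.octave][kp.layer], kp.xo, kp.yo, kp.angle,
                    kp.scl_octv, buf.data());
    for (int j = 0; j < 128; ++j) desc(i, j) = buf[j];
    out(i, 0) = kp.x * coord_scale + 1.0; // 1-based column (x)
    out(i, 1) = kp.y * coord_scale + 1.0; // 1-based row (y)
    out(i, 2) = kp.scale * coord_scale;
    out(i, 3) = kp.angle;
    out(i, 4) = kp.response;
  }
  return List::create(_["keypoints"] = out, _["descriptors"] = desc);
}
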