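// Translation-search mismatch score between a probe sub-region and a larger
// gallery sub-region: over all non-negative integer offsets the probe fits
// at, the fraction of mismatching pixels is minimized.  The scan keeps a
// running best count and aborts an offset as soon as it is beaten.
#include <Rcpp.h>
using namespace Rcpp;

//' @noRd
// [[Rcpp::export(name = ".psi_min_cpp")]]
List psi_min_cpp(IntegerMatrix a, IntegerMatrix b, int type,
                 bool exclude_background) {
  // type 0: shape mismatch |P1 - P2| == 1; type 1: orientation P1 != P2
  // (identical on {0,1} inputs; kept separate for clarity of the contract)
  int ha = a.nrow(), wa = a.ncol(), hb = b.nrow(), wb = b.ncol();
  if (wb > wa || hb > ha)
    stop("probe sub-region must be no larger than the gallery sub-region");
  const int *pa = a.begin(), *pb = b.begin();
  int bx = 0, by = 0;
  if (!exclude_background) {
    // fixed denominator: integer mismatch counts with early abort
    long best = (long)wb * hb + 1;
    for (int x = 0; x <= wa - wb; ++x) {
      for (int y = 0; y <= ha - hb; ++y) {
        long mism = 0;
        for (int u = 0; u < wb; ++u) {
          const int *ca = pa + (size_t)(u + x) * ha + y;
          const int *cb = pb + (size_t)u * hb;
          for (int v = 0; v < hb; ++v)
            mism += (ca[v] != cb[v]);
          if (mism >= best) break;
        }
        if (mism < best) {
          best = mism;
          bx = x;
          by = y;
        }
      }
    }
    return List::create(_["psi"] = (double)best / ((double)wb * hb),
                        _["x"] = bx, _["y"] = by);
  }
  // variable denominator: pixel pairs where both codes are background are
  // dropped; an all-background window scores 0
  double bestf = R_PosInf;
  for (int x = 0; x <= wa - wb; ++x) {
    for (int y = 0; y <= ha - hb; ++y) {
      long mism = 0, denom = 0;
      for (int u = 0; u < wb; ++u) {
        const int *ca = pa + (size_t)(u + x) * ha + y;
        const int *cb = pb + (size_t)u * hb;
        for (int v = 0; v < hb; ++v) {
          if (ca[v] == 0 && cb[v] == 0) continue;
          ++denom;
          mism += (ca[v] != cb[v]);
        }
      }
      double frac = denom > 0 ? (double)mism / denom : 0.0;
      if (frac < bestf) {
        bestf = frac;
        bx = x;
        by = y;
      }
    }
  }
  return List::create(_["psi"] = bestf, _["x"] = bx, _["y"] = by);
}
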