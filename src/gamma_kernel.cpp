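#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Low-style gamma by discrete offset search with bilinear interpolation of
// the evaluated image. Offsets are visited in increasing distance so the
// per-pixel search can stop as soon as the distance term alone exceeds the
// best gamma found (the dose term is non-negative).

struct Offset {
  double dr, dc, dist2norm; // row/col offset in pixels; (d/distTol)^2
};

// [[Rcpp::export]]
NumericMatrix cpp_gamma_map(NumericMatrix ref, NumericMatrix ev,
                            NumericMatrix doseTolAbs, LogicalMatrix evaluate,
                            double pitchMm, double distTolMm,
                            double radiusMm, double stepMm) {
  const int nr = ref.nrow(), nc = ref.ncol();
  const int K = (int)std::floor(radiusMm / stepMm + 1e-9);
  std::vector<Offset> offs;
  offs.reserve((2 * K + 1) * (2 * K + 1));
  for (int a = -K; a <= K; ++a) {
    for (int b = -K; b <= K; ++b) {
      double dy = a * stepMm, dx = b * stepMm;
      double d2 = dy * dy + dx * dx;
      if (d2 > radiusMm * radiusMm + 1e-9) continue;
      Offset o;
      o.dr = dy / pitchMm;
      o.dc = dx / pitchMm;
      o.dist2norm = d2 / (distTolMm * distTolMm);
      offs.push_back(o);
    }
  }
  std::sort(offs.begin(), offs.end(),
            [](const Offset &u, const Offset &v) {
              return u.dist2norm < v.dist2norm;
            });

  NumericMatrix out(nr, nc);
  for (int j = 0; j < nr; ++j) {
    for (int i = 0; i < nc; ++i) {
      if (!evaluate(j, i)) { out(j, i) = NA_REAL; continue; }
      const double rdose = ref(j, i);
      const double dtol = doseTolAbs(j, i);
      double best = R_PosInf;
      for (const Offset &o : offs) {
        if (o.dist2norm >= best) break; // sorted: no better offset remains
        double rr = j + o.dr, cc = i + o.dc;
        if (rr < 0 || rr > nr - 1 || cc < 0 || cc > nc - 1) continue;
        int j0 = (int)std::floor(rr); if (j0 > nr - 2) j0 = nr - 2;
        int i0 = (int)std::floor(cc); if (i0 > nc - 2) i0 = nc - 2;
        double fy = rr - j0, fx = cc - i0;
        double v = ev(j0, i0) * (1 - fx) * (1 - fy) +
                   ev(j0, i0 + 1) * fx * (1 - fy) +
                   ev(j0 + 1, i0) * (1 - fx) * fy +
                   ev(j0 + 1, i0 + 1) * fx * fy;
        double dd = (v - rdose) / dtol;
        double g2 = o.dist2norm + dd * dd;
        if (g2 < best) best = g2;
      }
      out(j, i) = std::sqrt(best);
    }
  }
  return out;
}
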