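#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Bilinear interpolation on a grid; (fy, fx) in fractional pixel units.
// Returns NA outside the grid extent.
static inline double bilinear(const NumericMatrix &v, double fy, double fx) {
  int nr = v.nrow(), nc = v.ncol();
  if (fy < 0 || fx < 0 || fy > nr - 1 || fx > nc - 1)
    return NA_REAL;
  int y0 = (int)std::floor(fy), x0 = (int)std::floor(fx);
  if (y0 == nr - 1) y0--;
  if (x0 == nc - 1) x0--;
  double ty = fy - y0, tx = fx - x0;
  return v(y0, x0) * (1 - ty) * (1 - tx) + v(y0 + 1, x0) * ty * (1 - tx) +
         v(y0, x0 + 1) * (1 - ty) * tx + v(y0 + 1, x0 + 1) * ty * tx;
}

struct Offset {
  double dy, dx, d2;
};

// Gamma map with local sub-pixel search: offsets on a regular stepMM grid
// within searchFactor * distTol of each reference point, dose interpolated
// bilinearly on the evaluated grid. Offsets are scanned in order of
// increasing distance so the distance term alone prunes the search exactly.
// [[Rcpp::export(name = ".gammaEngine")]]
List gammaEngine(NumericMatrix refVals, NumericVector refSpacing,
                 NumericVector refOrigin, NumericMatrix evalVals,
                 NumericVector evalSpacing, NumericVector evalOrigin,
                 double doseTolPct, double distTol, double cutoffPct,
                 double searchFactor, double stepMM) {
  double maxRef = 0;
  for (int i = 0; i < refVals.size(); i++)
    maxRef = std::max(maxRef, refVals[i]);
  double delta = doseTolPct / 100.0 * maxRef;   // dose tolerance, abs units
  double cutoff = cutoffPct / 100.0 * maxRef;
  double radius = searchFactor * distTol;

  std::vector<Offset> offs;
  int nsteps = (int)std::floor(radius / stepMM);
  for (int iy = -nsteps; iy <= nsteps; iy++)
    for (int ix = -nsteps; ix <= nsteps; ix++) {
      double dy = iy * stepMM, dx = ix * stepMM, d2 = dy * dy + dx * dx;
      if (d2 <= radius * radius + 1e-12)
        offs.push_back({dy, dx, d2});
    }
  std::sort(offs.begin(), offs.end(),
            [](const Offset &a, const Offset &b) { return a.d2 < b.d2; });

  int nr = refVals.nrow(), nc = refVals.ncol();
  NumericMatrix gamma(nr, nc);
  std::fill(gamma.begin(), gamma.end(), NA_REAL);
  double dt2 = distTol * distTol, dd2 = delta * delta;
  long nEval = 0, nPass = 0;
  bool anyOverlap = false;
  for (int r = 0; r < nr; r++) {
    for (int c = 0; c < nc; c++) {
      double dref = refVals(r, c);
      if (dref < cutoff) continue;
      double py = refOrigin[0] + r * refSpacing[0];
      double px = refOrigin[1] + c * refSpacing[1];
      double best = R_PosInf;
      for (const Offset &o : offs) {
        double distTerm = o.d2 / dt2;
        if (distTerm >= best) break;   // offsets sorted by distance: exact
        double fy = (py + o.dy - evalOrigin[0]) / evalSpacing[0];
        double fx = (px + o.dx - evalOrigin[1]) / evalSpacing[1];
        double dv = bilinear(evalVals, fy, fx);
        if (ISNA(dv)) continue;
        anyOverlap = true;
        double diff = dv - dref;
        double g2 = distTerm + diff * diff / dd2;
        if (g2 < best) best = g2;
      }
      if (!std::isfinite(best)) continue;  // no evaluated point in range
      double g = std::sqrt(best);
      gamma(r, c) = g;
      nEval++;
      if (g <= 1.0 + 1e-9) nPass++;
    }
  }
  return List::create(_["gamma"] = gamma, _["nEvaluated"] = (double)nEval,
                      _["nPass"] = (double)nPass,
                      _["anyOverlap"] = anyOverlap);
}

// Brute-force oracle: exhaustive search over the evaluated grid upsampled
// upFactor-fold by bilinear interpolation, no search-radius restriction.
// Rows whose pure distance term already exceeds the current best are
// skipped, which cannot change the minimum.
// [[Rcpp::export(name = ".gammaBruteEngine")]]
List gammaBruteEngine(NumericMatrix refVals, NumericVector refSpacing,
                      NumericVector refOrigin, NumericMatrix evalVals,
                      NumericVector evalSpacing, NumericVector evalOrigin,
                      double doseTolPct, double distTol, double cutoffPct,
                      int upFactor) {
  double maxRef = 0;
  for (int i = 0; i < refVals.size(); i++)
    maxRef = std::max(maxRef, refVals[i]);
  double delta = doseTolPct / 100.0 * maxRef;
  double cutoff = cutoffPct / 100.0 * maxRef;

  int enr = evalVals.nrow(), enc = evalVals.ncol();
  int unr = (enr - 1) * upFactor + 1, unc = (enc - 1) * upFactor + 1;
  std::vector<double> up((size_t)unr * unc);
  std::vector<double> upy(unr), upx(unc);
  for (int r = 0; r < unr; r++)
    upy[r] = evalOrigin[0] + r * evalSpacing[0] / upFactor;
  for (int c = 0; c < unc; c++)
    upx[c] = evalOrigin[1] + c * evalSpacing[1] / upFactor;
  for (int r = 0; r < unr; r++)
    for (int c = 0; c < unc; c++)
      up[(size_t)r * unc + c] =
          bilinear(evalVals, (double)r / upFactor, (double)c / upFactor);

  int nr = refVals.nrow(), nc = refVals.ncol();
  NumericMatrix gamma(nr, nc);
  std::fill(gamma.begin(), gamma.end(), NA_REAL);
  double dt2 = distTol * distTol, dd2 = delta * delta;
  long nEval = 0, nPass = 0;
  for (int r = 0; r < nr; r++) {
    for (int c = 0; c < nc; c++) {
      double dref = refVals(r, c);
      if (dref < cutoff) continue;
      double py = refOrigin[0] + r * refSpacing[0];
      double px = refOrigin[1] + c * refSpacing[1];
      double best = R_PosInf;
      for (int ur = 0; ur < unr; ur++) {
        double dy = upy[ur] - py;
        double rowTerm = dy * dy / dt2;
        if (rowTerm >= best) continue;
        const double *rowPtr = &up[(size_t)ur * unc];
        for (int uc = 0; uc < unc; uc++) {
          double dx = upx[uc] - px;
          double distTerm = rowTerm + dx * dx / dt2;
          if (distTerm >= best) continue;
          double diff = rowPtr[uc] - dref;
          double g2 = distTerm + diff * diff / dd2;
          if (g2 < best) best = g2;
        }
      }
      if (!std::isfinite(best)) continue;
      gamma(r, c) = std::sqrt(best);
      nEval++;
      if (gamma(r, c) <= 1.0 + 1e-9) nPass++;
    }
  }
  return List::create(_["gamma"] = gamma, _["nEvaluated"] = (double)nEval,
                      _["nPass"] = (double)nPass);
}
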