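#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Harmonic bonded energy: U = sum 1/2 kb (r - r0)^2 + sum 1/2 kt (th - th0)^2
// (force constants arrive pre-converted to the half-k convention).
static double totalEnergy(const std::vector<double> &c,
                          const IntegerMatrix &bonds,
                          const NumericVector &bondR0,
                          const NumericVector &bondK,
                          const IntegerMatrix &angles,
                          const NumericVector &angleTh0,
                          const NumericVector &angleK) {
  double U = 0.0;
  for (int b = 0; b < bonds.nrow(); ++b) {
    const int i = 3 * bonds(b, 0), j = 3 * bonds(b, 1);
    const double dx = c[i] - c[j], dy = c[i + 1] - c[j + 1],
                 dz = c[i + 2] - c[j + 2];
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    const double d = r - bondR0[b];
    U += 0.5 * bondK[b] * d * d;
  }
  for (int a = 0; a < angles.nrow(); ++a) {
    const int i = 3 * angles(a, 0), j = 3 * angles(a, 1),
              k = 3 * angles(a, 2);
    const double v1x = c[i] - c[j], v1y = c[i + 1] - c[j + 1],
                 v1z = c[i + 2] - c[j + 2];
    const double v2x = c[k] - c[j], v2y = c[k + 1] - c[j + 1],
                 v2z = c[k + 2] - c[j + 2];
    const double n1 = std::sqrt(v1x * v1x + v1y * v1y + v1z * v1z);
    const double n2 = std::sqrt(v2x * v2x + v2y * v2y + v2z * v2z);
    double cth = (v1x * v2x + v1y * v2y + v1z * v2z) / (n1 * n2);
    if (cth > 1.0) cth = 1.0;
    if (cth < -1.0) cth = -1.0;
    const double d = std::acos(cth) - angleTh0[a];
    U += 0.5 * angleK[a] * d * d;
  }
  return U;
}

// Metropolis Monte Carlo in Cartesian coordinates of the movable atoms.
// Uses R's RNG so a set.seed() in the caller makes runs bit-reproducible.
// Frames (movable-atom coordinates) are emitted every `stride`
// accepted-or-rejected steps after `burnIn`.
// [[Rcpp::export(name = ".mcSample")]]
List mcSample(NumericVector coords0, IntegerVector movable,
              IntegerMatrix bonds, NumericVector bondR0, NumericVector bondK,
              IntegerMatrix angles, NumericVector angleTh0,
              NumericVector angleK, double kT, int nSteps, int burnIn,
              int stride, double maxStep, bool autotune) {
  RNGScope scope;
  std::vector<double> c(coords0.begin(), coords0.end());
  const int nMov = movable.size();
  const int nFrames = nSteps / stride;
  NumericMatrix frames(nFrames, 3 * nMov);

  double U = totalEnergy(c, bonds, bondR0, bondK, angles, angleTh0, angleK);
  int accWin = 0, winLen = 0, accProd = 0, nProd = 0, frame = 0;
  const int tuneEvery = 200;

  for (int step = 1; step <= burnIn + nSteps; ++step) {
    const int a = movable[(int)std::floor(unif_rand() * nMov) % nMov];
    const int off = 3 * a;
    double old_[3] = {c[off], c[off + 1], c[off + 2]};
    for (int d = 0; d < 3; ++d)
      c[off + d] += (2.0 * unif_rand() - 1.0) * maxStep;
    const double Unew =
        totalEnergy(c, bonds, bondR0, bondK, angles, angleTh0, angleK);
    bool accept = Unew <= U || unif_rand() < std::exp(-(Unew - U) / kT);
    if (accept) {
      U = Unew;
      ++accWin;
    } else {
      for (int d = 0; d < 3; ++d) c[off + d] = old_[d];
    }
    ++winLen;
    if (step <= burnIn) {
      if (autotune && winLen == tuneEvery) {
        const double frac = (double)accWin / winLen;
        if (frac > 0.45) maxStep *= 1.1;        // target ~40% acceptance
        else if (frac < 0.35) maxStep *= 0.9;
        accWin = 0;
        winLen = 0;
      }
      if (step == burnIn) { accWin = 0; winLen = 0; }
    } else {
      nProd += 1;
      accProd += accept ? 1 : 0;
      const int prod = step - burnIn;
      if (prod % stride == 0 && frame < nFrames) {
        for (int m = 0; m < nMov; ++m)
          for (int d = 0; d < 3; ++d)
            frames(frame, 3 * m + d) = c[3 * movable[m] + d];
        ++frame;
      }
    }
  }
  return List::create(_["frames"] = frames,
                      _["acceptance"] = nProd ? (double)accProd / nProd : NA_REAL,
                      _["maxStep"] = maxStep,
                      _["finalEnergy"] = U);
}
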