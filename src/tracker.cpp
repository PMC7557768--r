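// Probabilistic streamline propagation over a discrete-lobe orientation
// field. Steps follow circular arcs of fixed arc length whose initial
// tangent is the previous direction and whose final tangent is the sampled
// direction; direction sampling is amplitude-weighted rejection sampling
// restricted to a cone around the previous direction, with antipodal sign
// resolution. Uses R's RNG (via Rcpp) so set.seed() governs determinism.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Field {
  IntegerVector dims;
  NumericMatrix invAffine;   // world -> continuous voxel index
  IntegerVector offsets;     // length nvox + 1
  NumericMatrix dirs;        // L x 3 unit directions
  NumericVector amps;        // L amplitudes
};

inline bool voxelOf(const Field& f, const double p[3], int v[3]) {
  for (int r = 0; r < 3; ++r) {
    double c = f.invAffine(r, 0) * p[0] + f.invAffine(r, 1) * p[1] +
               f.invAffine(r, 2) * p[2] + f.invAffine(r, 3);
    v[r] = (int)std::floor(c + 0.5);  // half-open [i-0.5, i+0.5)
    if (v[r] < 0 || v[r] >= f.dims[r]) return false;
  }
  return true;
}

inline int linIndex(const Field& f, const int v[3]) {
  return v[0] + f.dims[0] * (v[1] + f.dims[1] * v[2]);
}

// amplitude-weighted draw among lobes with amp >= cutoff; returns lobe row
// or -1 when no lobe passes the cutoff
inline int drawLobe(const Field& f, int lin, double cutoff) {
  int a = f.offsets[lin], b = f.offsets[lin + 1];
  double total = 0.0;
  for (int i = a; i < b; ++i)
    if (f.amps[i] >= cutoff) total += f.amps[i];
  if (total <= 0.0) return -1;
  double u = R::runif(0.0, total);
  double acc = 0.0;
  for (int i = a; i < b; ++i) {
    if (f.amps[i] < cutoff) continue;
    acc += f.amps[i];
    if (u <= acc) return i;
  }
  return b - 1;
}

// sample a direction at p: cone-restricted when prev != nullptr
// returns true and fills out[3]; false = termination signal
inline bool sampleDir(const Field& f, const double p[3], const double* prev,
                      double cosMax, double cutoff, int maxTrials,
                      double out[3]) {
  int v[3];
  if (!voxelOf(f, p, v)) return false;
  int lin = linIndex(f, v);
  for (int trial = 0; trial < maxTrials; ++trial) {
    int l = drawLobe(f, lin, cutoff);
    if (l < 0) return false;  // no lobe reaches the cutoff
    double d[3] = { f.dirs(l, 0), f.dirs(l, 1), f.dirs(l, 2) };
    if (prev) {
      double dot = d[0] * prev[0] + d[1] * prev[1] + d[2] * prev[2];
      if (dot < 0) { d[0] = -d[0]; d[1] = -d[1]; d[2] = -d[2]; dot = -dot; }
      if (dot < cosMax) continue;  // outside the cone: rejected
    }
    out[0] = d[0]; out[1] = d[1]; out[2] = d[2];
    return true;
  }
  return false;
}

// advance one circular-arc step: initial tangent t, final tangent d,
// arc length 'step'; chord length 2 (step/theta) sin(theta/2) along the
// bisector of t and d (straight segment when the tangents coincide)
inline void arcStep(const double p[3], const double t[3], const double d[3],
                    double step, double pn[3]) {
  double dot = t[0] * d[0] + t[1] * d[1] + t[2] * d[2];
  if (dot > 1.0) dot = 1.0;
  if (dot < -1.0) dot = -1.0;
  double theta = std::acos(dot);
  if (theta < 1e-9) {
    for (int k = 0; k < 3; ++k) pn[k] = p[k] + step * d[k];
    return;
  }
  double chord = 2.0 * (step / theta) * std::sin(theta / 2.0);
  double b[3] = { t[0] + d[0], t[1] + d[1], t[2] + d[2] };
  double nb = std::sqrt(b[0] * b[0] + b[1] * b[1] + b[2] * b[2]);
  for (int k = 0; k < 3; ++k) pn[k] = p[k] + chord * b[k] / nb;
}

// one half-track from seed with initial tangent t0 (seed point excluded)
void halfTrack(const Field& f, const double seed[3], const double t0[3],
               double step, double cosMax, double cutoff, double maxLen,
               int maxTrials, std::vector<double>& pts) {
  double p[3] = { seed[0], seed[1], seed[2] };
  double t[3] = { t0[0], t0[1], t0[2] };
  double len = 0.0;
  int v[3];
  while (len + step <= maxLen) {
    if (!voxelOf(f, p, v)) break;  // exited the grid
    double d[3];
    if (!sampleDir(f, p, t, cosMax, cutoff, maxTrials, d)) break;
    double pn[3];
    arcStep(p, t, d, step, pn);
    pts.push_back(pn[0]); pts.push_back(pn[1]); pts.push_back(pn[2]);
    p[0] = pn[0]; p[1] = pn[1]; p[2] = pn[2];
    t[0] = d[0]; t[1] = d[1]; t[2] = d[2];
    len += step;
  }
}

} // namespace

// [[Rcpp::export(name = ".cppSampleDirections")]]
NumericMatrix cppSampleDirections(IntegerVector dims, NumericMatrix invAffine,
                                  IntegerVector offsets, NumericMatrix dirs,
                                  NumericVector amps, NumericVector point,
                                  Nullable<NumericVector> prev,
                                  double maxAngleDeg, double cutoff,
                                  int maxTrials, int n) {
  Field f{dims, invAffine, offsets, dirs, amps};
  double p[3] = { point[0], point[1], point[2] };
  int v[3];
  if (!voxelOf(f, p, v)) stop("sample_direction: point outside grid");
  double cosMax = std::cos(maxAngleDeg * M_PI / 180.0);
  double pv[3];
  const double* pp = nullptr;
  if (prev.isNotNull()) {
    NumericVector q(prev);
    pv[0] = q[0]; pv[1] = q[1]; pv[2] = q[2];
    pp = pv;
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double d[3];
    if (sampleDir(f, p, pp, cosMax, cutoff, maxTrials, d)) {
      out(i, 0) = d[0]; out(i, 1) = d[1]; out(i, 2) = d[2];
    } else {
      out(i, 0) = NA_REAL; out(i, 1) = NA_REAL; out(i, 2) = NA_REAL;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cppTrack")]]
List cppTrack(IntegerVector dims, NumericMatrix invAffine,
              IntegerVector offsets, NumericMatrix dirs, NumericVector amps,
              NumericMatrix seeds, double step, double maxAngleDeg,
              double cutoff, double maxLen, int minPoints, int maxTrials) {
  Field f{dims, invAffine, offsets, dirs, amps};
  double cosMax = std::cos(maxAngleDeg * M_PI / 180.0);
  std::vector<NumericMatrix> kept;
  for (int s = 0; s < seeds.nrow(); ++s) {
    double seed[3] = { seeds(s, 0), seeds(s, 1), seeds(s, 2) };
    int v[3];
    if (!voxelOf(f, seed, v)) continue;  // seed fell outside the grid
    double d0[3];
    // initial orientation: unrestricted amplitude-weighted draw
    if (!sampleDir(f, seed, nullptr, cosMax, cutoff, maxTrials, d0))
      continue;  // seed voxel below cutoff
    std::vector<double> fwd, bwd;
    halfTrack(f, seed, d0, step, cosMax, cutoff, maxLen, maxTrials, fwd);
    double d0n[3] = { -d0[0], -d0[1], -d0[2] };
    halfTrack(f, seed, d0n, step, cosMax, cutoff, maxLen, maxTrials, bwd);
    int nb = (int)bwd.size() / 3, nf = (int)fwd.size() / 3;
    int n = nb + 1 + nf;
    if (n < minPoints) continue;
    NumericMatrix m(n, 3);
    for (int i = 0; i < nb; ++i)        // backward half, reversed
      for (int k = 0; k < 3; ++k) m(i, k) = bwd[3 * (nb - 1 - i) + k];
    for (int k = 0; k < 3; ++k) m(nb, k) = seed[k];
    for (int i = 0; i < nf; ++i)
      for (int k = 0; k < 3; ++k) m(nb + 1 + i, k) = fwd[3 * i + k];
    kept.push_back(m);
  }
  List out(kept.size());
  for (size_t i = 0; i < kept.size(); ++i) out[i] = kept[i];
  return out;
}
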