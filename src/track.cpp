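// Deterministic streamline integration (fixed-step RK2) over a per-voxel
// peak-direction field, with trilinear direction interpolation, previous-step
// sign alignment, FA and turning-angle termination. Coordinates here are
// continuous 0-based voxel indices; the R wrapper converts to world mm.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Field {
  const double *peaks; // nvox x maxp x 3
  const int *npeaks;   // nvox
  const double *fa;    // nvox
  int nx, ny, nz, maxp;
  R_xlen_t nvox;
};

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static double trilin_fa(const Field &f, double x, double y, double z) {
  x = clampd(x, 0, f.nx - 1);
  y = clampd(y, 0, f.ny - 1);
  z = clampd(z, 0, f.nz - 1);
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = x0 + 1 < f.nx ? x0 + 1 : x0;
  int y1 = y0 + 1 < f.ny ? y0 + 1 : y0;
  int z1 = z0 + 1 < f.nz ? z0 + 1 : z0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  #define V(i, j, k) f.fa[(i) + (R_xlen_t)f.nx * ((j) + (R_xlen_t)f.ny * (k))]
  double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
  double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
  double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
  double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
  #undef V
  return (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
         (c01 * (1 - fy) + c11 * fy) * fz;
}

// best peak at voxel (i,j,k) w.r.t. reference direction; sign-aligned
static bool best_peak(const Field &f, int i, int j, int k,
                      const double ref[3], double out[3]) {
  R_xlen_t v = i + (R_xlen_t)f.nx * (j + (R_xlen_t)f.ny * k);
  int n = f.npeaks[v];
  if (n <= 0) return false;
  double best = -1.0, sgn = 1.0;
  int bi = -1;
  for (int p = 0; p < n; ++p) {
    double px = f.peaks[v + f.nvox * (p + (R_xlen_t)0 * f.maxp)];
    double py = f.peaks[v + f.nvox * (p + (R_xlen_t)1 * f.maxp)];
    double pz = f.peaks[v + f.nvox * (p + (R_xlen_t)2 * f.maxp)];
    double d = px * ref[0] + py * ref[1] + pz * ref[2];
    double a = std::fabs(d);
    if (a > best) { best = a; bi = p; sgn = d >= 0 ? 1.0 : -1.0; }
  }
  if (bi < 0) return false;
  out[0] = sgn * f.peaks[v + f.nvox * (bi + (R_xlen_t)0 * f.maxp)];
  out[1] = sgn * f.peaks[v + f.nvox * (bi + (R_xlen_t)1 * f.maxp)];
  out[2] = sgn * f.peaks[v + f.nvox * (bi + (R_xlen_t)2 * f.maxp)];
  return true;
}

// trilinearly weighted direction at a continuous point, aligned to ref
static bool interp_dir(const Field &f, const double p[3], const double ref[3],
                       double out[3]) {
  double x = p[0], y = p[1], z = p[2];
  if (x < 0 || y < 0 || z < 0 || x > f.nx - 1 || y > f.ny - 1 || z > f.nz - 1)
    return false;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = x0 + 1 < f.nx ? x0 + 1 : x0;
  int y1 = y0 + 1 < f.ny ? y0 + 1 : y0;
  int z1 = z0 + 1 < f.nz ? z0 + 1 : z0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  int xi[2] = {x0, x1}; double wx[2] = {1 - fx, fx};
  int yi[2] = {y0, y1}; double wy[2] = {1 - fy, fy};
  int zi[2] = {z0, z1}; double wz[2] = {1 - fz, fz};
  double acc[3] = {0, 0, 0}, wt = 0;
  for (int a = 0; a < 2; ++a)
    for (int b = 0; b < 2; ++b)
      for (int c = 0; c < 2; ++c) {
        double w = wx[a] * wy[b] * wz[c];
        if (w <= 1e-12) continue;
        double pk[3];
        if (!best_peak(f, xi[a], yi[b], zi[c], ref, pk)) continue;
        acc[0] += w * pk[0]; acc[1] += w * pk[1]; acc[2] += w * pk[2];
        wt += w;
      }
  if (wt < 1e-3) return false;
  double nrm = std::sqrt(acc[0] * acc[0] + acc[1] * acc[1] + acc[2] * acc[2]);
  if (nrm < 1e-12) return false;
  out[0] = acc[0] / nrm; out[1] = acc[1] / nrm; out[2] = acc[2] / nrm;
  return true;
}

// integrate one direction from seed; appends points (not including seed)
static void track_one_way(const Field &f, const double seed[3],
                          const double d0[3], double step, double cos_max,
                          double fa_stop, int max_steps,
                          std::vector<double> &pts) {
  double p[3] = {seed[0], seed[1], seed[2]};
  double ref[3] = {d0[0], d0[1], d0[2]};
  for (int s = 0; s < max_steps; ++s) {
    double v1[3];
    if (!interp_dir(f, p, ref, v1)) break;
    double pm[3] = {p[0] + 0.5 * step * v1[0], p[1] + 0.5 * step * v1[1],
                    p[2] + 0.5 * step * v1[2]};
    double v2[3];
    if (!interp_dir(f, pm, v1, v2)) break;
    double ca = ref[0] * v2[0] + ref[1] * v2[1] + ref[2] * v2[2];
    if (ca < cos_max) break;
    double pn[3] = {p[0] + step * v2[0], p[1] + step * v2[1],
                    p[2] + step * v2[2]};
    if (pn[0] < 0 || pn[1] < 0 || pn[2] < 0 || pn[0] > f.nx - 1 ||
        pn[1] > f.ny - 1 || pn[2] > f.nz - 1)
      break;
    if (trilin_fa(f, pn[0], pn[1], pn[2]) < fa_stop) break;
    pts.push_back(pn[0]); pts.push_back(pn[1]); pts.push_back(pn[2]);
    p[0] = pn[0]; p[1] = pn[1]; p[2] = pn[2];
    ref[0] = v2[0]; ref[1] = v2[1]; ref[2] = v2[2];
  }
}

// [[Rcpp::export]]
List cpp_track(NumericVector peaks, IntegerVector npeaks, NumericVector fa,
               IntegerVector dims, IntegerMatrix seeds, double step,
               double max_angle_deg, double fa_stop, int max_steps,
               int min_points) {
  Field f;
  f.nx = dims[0]; f.ny = dims[1]; f.nz = dims[2];
  f.nvox = (R_xlen_t)f.nx * f.ny * f.nz;
  f.maxp = peaks.size() / (f.nvox * 3);
  f.peaks = REAL(peaks);
  f.npeaks = INTEGER(npeaks);
  f.fa = REAL(fa);
  double cos_max = std::cos(max_angle_deg * M_PI / 180.0);

  std::vector<NumericMatrix> kept;
  std::vector<int> kept_seed;
  for (int s = 0; s < seeds.nrow(); ++s) {
    int i = seeds(s, 0), j = seeds(s, 1), k = seeds(s, 2);
    double seed[3] = {(double)i, (double)j, (double)k};
    double d0[3];
    double ref0[3] = {1, 0, 0}; // any reference; largest peak wins by |dot|
    R_xlen_t v = i + (R_xlen_t)f.nx * (j + (R_xlen_t)f.ny * k);
    if (f.npeaks[v] <= 0) continue;
    // principal peak: stored first
    d0[0] = f.peaks[v + f.nvox * (R_xlen_t)0];
    d0[1] = f.peaks[v + f.nvox * ((R_xlen_t)1 * f.maxp)];
    d0[2] = f.peaks[v + f.nvox * ((R_xlen_t)2 * f.maxp)];
    (void)ref0;
    std::vector<double> fwd, bwd;
    track_one_way(f, seed, d0, step, cos_max, fa_stop, max_steps, fwd);
    double d0n[3] = {-d0[0], -d0[1], -d0[2]};
    track_one_way(f, seed, d0n, step, cos_max, fa_stop, max_steps, bwd);
    int nf = fwd.size() / 3, nb = bwd.size() / 3;
    int npts = nf + nb + 1;
    if (npts < min_points || npts < 2) continue;
    NumericMatrix m(npts, 3);
    for (int q = 0; q < nb; ++q) { // backward points, reversed
      int row = nb - 1 - q;
      m(row, 0) = bwd[q * 3]; m(row, 1) = bwd[q * 3 + 1];
      m(row, 2) = bwd[q * 3 + 2];
    }
    m(nb, 0) = seed[0]; m(nb, 1) = seed[1]; m(nb, 2) = seed[2];
    for (int q = 0; q < nf; ++q) {
      m(nb + 1 + q, 0) = fwd[q * 3]; m(nb + 1 + q, 1) = fwd[q * 3 + 1];
      m(nb + 1 + q, 2) = fwd[q * 3 + 2];
    }
    kept.push_back(m);
    kept_seed.push_back(s + 1);
  }
  List out((int)kept.size());
  for (int q = 0; q < (int)kept.size(); ++q) out[q] = kept[q];
  return List::create(_["streamlines"] = out,
                      _["seed_index"] = wrap(kept_seed));
}
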