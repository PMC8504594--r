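// Photon Monte Carlo kernel: delta (Woodcock) tracking through the labeled
// voxel scene with Klein-Nishina incoherent scattering, Thomson-law coherent
// scattering and local (kerma-approximation) energy deposition.
//
// Material data arrive as per-label linear-attenuation and channel-fraction
// tables on a uniform energy grid; the kernel itself is material-agnostic.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

// --- deterministic, platform-independent RNG (splitmix64 -> xoshiro256+) ---
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1); never exactly 0 so -log(u) is finite
  double runif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

const double MEC2 = 510.99895; // electron rest energy, keV

// Klein-Nishina polar-angle sampling by rejection (bound: f(cos=1) = 2)
double kn_sample_cost(Xoshiro &rng, double e_kev) {
  const double k = e_kev / MEC2;
  for (;;) {
    double c = 2.0 * rng.runif() - 1.0;
    double r = 1.0 / (1.0 + k * (1.0 - c));
    double f = r + r * r * r - r * r * (1.0 - c * c);
    if (2.0 * rng.runif() < f) return c;
  }
}

// Thomson angular law (1 + cos^2)/2 by rejection
double thomson_sample_cost(Xoshiro &rng) {
  for (;;) {
    double c = 2.0 * rng.runif() - 1.0;
    if (2.0 * rng.runif() < 1.0 + c * c) return c;
  }
}

void rotate_direction(double *d, double cost, double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double cphi = std::cos(phi), sphi = std::sin(phi);
  double a = std::sqrt(std::max(0.0, 1.0 - d[2] * d[2]));
  double nd[3];
  if (a > 1e-10) {
    nd[0] = cost * d[0] + sint * (d[0] * d[2] * cphi - d[1] * sphi) / a;
    nd[1] = cost * d[1] + sint * (d[1] * d[2] * cphi + d[0] * sphi) / a;
    nd[2] = cost * d[2] - sint * a * cphi;
  } else {
    double sgn = d[2] > 0 ? 1.0 : -1.0;
    nd[0] = sint * cphi; nd[1] = sint * sphi; nd[2] = cost * sgn;
  }
  double norm = std::sqrt(nd[0]*nd[0] + nd[1]*nd[1] + nd[2]*nd[2]);
  d[0] = nd[0] / norm; d[1] = nd[1] / norm; d[2] = nd[2] / norm;
}

struct Source {
  std::vector<double> edges, cdf;
  double bin_width;
  double focal[3];
  double rect[4];   // x0, x1, y0, y1 on the entry plane
  double zplane;
  bool parallel;

  double sample_energy(Xoshiro &rng) const {
    double u = rng.runif();
    size_t lo = std::upper_bound(cdf.begin(), cdf.end(), u) - cdf.begin();
    if (lo >= edges.size()) lo = edges.size() - 1;
    return edges[lo] + rng.runif() * bin_width;
  }
  void sample(Xoshiro &rng, double *pos, double *dir, double &e) const {
    e = sample_energy(rng);
    double tx = rect[0] + rng.runif() * (rect[1] - rect[0]);
    double ty = rect[2] + rng.runif() * (rect[3] - rect[2]);
    pos[0] = tx; pos[1] = ty; pos[2] = zplane;
    if (parallel) {
      dir[0] = 0.0; dir[1] = 0.0; dir[2] = -1.0;
    } else {
      double dx = tx - focal[0], dy = ty - focal[1], dz = zplane - focal[2];
      double n = std::sqrt(dx*dx + dy*dy + dz*dz);
      dir[0] = dx / n; dir[1] = dy / n; dir[2] = dz / n;
    }
  }
};

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_sample_compton")]]
NumericMatrix cpp_sample_compton(double energy_kev, int n, double seed) {
  Xoshiro rng(static_cast<uint64_t>(seed));
  NumericMatrix out(n, 2);
  const double k = energy_kev / MEC2;
  for (int i = 0; i < n; ++i) {
    double c = kn_sample_cost(rng, energy_kev);
    out(i, 0) = energy_kev / (1.0 + k * (1.0 - c));
    out(i, 1) = std::acos(c);
  }
  colnames(out) = CharacterVector::create("energy", "angle");
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_sample_source")]]
List cpp_sample_source(NumericVector edges, NumericVector cdf,
                       double bin_width, NumericVector focal,
                       NumericVector rect, double zplane, bool parallel,
                       int n, double seed) {
  Source src;
  src.edges = as<std::vector<double>>(edges);
  src.cdf = as<std::vector<double>>(cdf);
  src.bin_width = bin_width;
  for (int i = 0; i < 3; ++i) src.focal[i] = focal[i];
  for (int i = 0; i < 4; ++i) src.rect[i] = rect[i];
  src.zplane = zplane;
  src.parallel = parallel;
  Xoshiro rng(static_cast<uint64_t>(seed));
  NumericVector e(n);
  NumericMatrix pos(n, 3), dir(n, 3);
  double p[3], d[3], ee;
  for (int i = 0; i < n; ++i) {
    src.sample(rng, p, d, ee);
    e[i] = ee;
    for (int j = 0; j < 3; ++j) { pos(i, j) = p[j]; dir(i, j) = d[j]; }
  }
  return List::create(_["energy"] = e, _["position"] = pos,
                      _["direction"] = dir);
}

//' @noRd
// [[Rcpp::export(name = ".cpp_run_transport")]]
List cpp_run_transport(IntegerVector labels, IntegerVector dims,
                       double voxel_cm, NumericVector origin,
                       NumericMatrix mu_tot,    // nE x nLab, 1/cm
                       NumericMatrix cum_pe,    // channel cdf: P(photoelectric)
                       NumericMatrix cum_inc,   // P(photoelectric or incoherent)
                       NumericVector mu_major,  // nE majorant, 1/cm
                       double e0, double de,
                       NumericVector edges, NumericVector cdf,
                       double bin_width, NumericVector focal,
                       NumericVector rect, double zplane, bool parallel,
                       NumericMatrix points, double point_radius_cm,
                       int n_histories, int n_batches, double seed,
                       double cutoff_kev, int max_steps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nE = mu_tot.nrow(), nLab = mu_tot.ncol();
  const int np = points.nrow();
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double bx = ox + nx * voxel_cm, by = oy + ny * voxel_cm,
               bz = oz + nz * voxel_cm;

  Source src;
  src.edges = as<std::vector<double>>(edges);
  src.cdf = as<std::vector<double>>(cdf);
  src.bin_width = bin_width;
  for (int i = 0; i < 3; ++i) src.focal[i] = focal[i];
  for (int i = 0; i < 4; ++i) src.rect[i] = rect[i];
  src.zplane = zplane;
  src.parallel = parallel;

  NumericMatrix dep(n_batches, nLab), pdep(n_batches, np);
  NumericVector emitted(n_batches);
  int warnings = 0;
  const double r2 = point_radius_cm * point_radius_cm;
  const int per_batch = n_histories / n_batches;
  const int remainder = n_histories % n_batches;

  for (int b = 0; b < n_batches; ++b) {
    // independent substream per (seed, batch)
    uint64_t x = static_cast<uint64_t>(seed);
    uint64_t mix = x ^ (0xA0761D6478BD642FULL * static_cast<uint64_t>(b + 1));
    Xoshiro rng(Xoshiro::splitmix(mix));
    const int nb = per_batch + (b < remainder ? 1 : 0);

    for (int h = 0; h < nb; ++h) {
      double pos[3], dir[3], E;
      src.sample(rng, pos, dir, E);
      emitted[b] += E;
      bool alive = true;
      int steps = 0;
      while (alive) {
        if (++steps > max_steps) { // livelock guard: dump and terminate
          int ix = (int)((pos[0] - ox) / voxel_cm),
              iy = (int)((pos[1] - oy) / voxel_cm),
              iz = (int)((pos[2] - oz) / voxel_cm);
          if (ix >= 0 && ix < nx && iy >= 0 && iy < ny && iz >= 0 && iz < nz) {
            int lab = labels[ix + nx * (iy + (R_xlen_t)ny * iz)];
            dep(b, lab) += E;
          }
          ++warnings;
          break;
        }
        int ei = (int)std::lround((E - e0) / de);
        if (ei < 0) ei = 0; else if (ei >= nE) ei = nE - 1;
        double mumax = mu_major[ei];
        double s = -std::log(rng.runif()) / mumax;
        pos[0] += s * dir[0]; pos[1] += s * dir[1]; pos[2] += s * dir[2];
        if (pos[0] < ox || pos[0] >= bx || pos[1] < oy || pos[1] >= by ||
            pos[2] < oz || pos[2] >= bz)
          break; // escaped the scene
        int ix = (int)((pos[0] - ox) / voxel_cm),
            iy = (int)((pos[1] - oy) / voxel_cm),
            iz = (int)((pos[2] - oz) / voxel_cm);
        int lab = labels[ix + nx * (iy + (R_xlen_t)ny * iz)];
        double mu = mu_tot(ei, lab);
        if (rng.runif() * mumax >= mu) continue; // virtual collision
        // real interaction: choose channel
        double u = rng.runif();
        double deposit = 0.0;
        if (u < cum_pe(ei, lab)) {            // photoelectric
          deposit = E;
          alive = false;
        } else if (u < cum_inc(ei, lab)) {    // incoherent (Compton)
          double c = kn_sample_cost(rng, E);
          double Ep = E / (1.0 + (E / MEC2) * (1.0 - c));
          deposit = E - Ep;
          if (Ep < cutoff_kev) {              // low-energy cutoff: dump locally
            deposit = E;
            alive = false;
          } else {
            rotate_direction(dir, c, 2.0 * M_PI * rng.runif());
            E = Ep;
          }
        } else {                              // coherent: redirect only
          double c = thomson_sample_cost(rng);
          rotate_direction(dir, c, 2.0 * M_PI * rng.runif());
        }
        if (deposit > 0.0) {
          dep(b, lab) += deposit;
          for (int q = 0; q < np; ++q) {
            double dx = pos[0] - points(q, 0), dy = pos[1] - points(q, 1),
                   dz = pos[2] - points(q, 2);
            if (dx*dx + dy*dy + dz*dz < r2) pdep(b, q) += deposit;
          }
        }
      }
    }
  }
  return List::create(_["deposit"] = dep, _["points"] = pdep,
                      _["emitted"] = emitted, _["warnings"] = warnings);
}
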