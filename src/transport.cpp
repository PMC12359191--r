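#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Deliberately simplified particle transport on a labeled voxel grid:
//  * charged particles travel a single straight track of length equal to
//    their CSDA range and deposit energy uniformly along it (constant LET),
//    apportioned to regions by exact ray/voxel traversal;
//  * photons fly exponential free paths sampled by Woodcock (delta)
//    tracking against per-region linear attenuation coefficients and
//    deposit their full energy at the first real interaction (kerma-style,
//    no secondaries).
// The grid bounding box is either reflective (position and direction
// mirrored) or escaping (energy beyond it is lost). Label 0 denotes void:
// nothing is deposited there, but tracks keep going (tallied in slot 0 so
// reflective-mode conservation remains checkable).

struct RNG { // xorshift128+, seeded via splitmix64
  uint64_t s0, s1;
  explicit RNG(uint64_t seed) {
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    auto mix = [](uint64_t& z) {
      z += 0x9E3779B97F4A7C15ULL;
      uint64_t x = z;
      x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
      x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
      return x ^ (x >> 31);
    };
    s0 = mix(z); s1 = mix(z);
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  inline uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  inline double unif() { // in (0,1)
    return (next() >> 11) * (1.0 / 9007199254740992.0) +
           (0.5 / 9007199254740992.0);
  }
};

struct Grid {
  const int* lab;
  int nx, ny, nz;
  double ox, oy, oz, hx, hy, hz;
  double x1, y1, z1; // far corner
  inline int region(double x, double y, double z) const {
    int i = (int)std::floor((x - ox) / hx);
    int j = (int)std::floor((y - oy) / hy);
    int k = (int)std::floor((z - oz) / hz);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return -1;
    return lab[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
  }
};

static inline void iso_dir(RNG& rng, double* d) {
  double z = 1.0 - 2.0 * rng.unif();
  double r = std::sqrt(std::max(0.0, 1.0 - z * z));
  double phi = 2.0 * M_PI * rng.unif();
  d[0] = r * std::cos(phi); d[1] = r * std::sin(phi); d[2] = z;
}

// Mirror a position into the box and flip the matching direction components
// (handles multiple reflections via folding).
static inline void reflect_fold(double& x, double lo, double hi, double& d) {
  double L = hi - lo;
  double t = (x - lo) / (2.0 * L);
  double u = (t - std::floor(t)) * 2.0 * L; // fmod without glibc fmod
  if (u > L) { u = 2.0 * L - u; d = -d; }
  x = lo + u;
}

// [[Rcpp::export(name = ".charged_transport")]]
List charged_transport(IntegerVector labels, IntegerVector dims,
                       NumericVector origin, NumericVector spacing,
                       NumericMatrix starts, double energy, double range,
                       bool reflective, int nregions, double seed) {
  Grid G;
  G.lab = INTEGER(labels);
  G.nx = dims[0]; G.ny = dims[1]; G.nz = dims[2];
  G.ox = origin[0]; G.oy = origin[1]; G.oz = origin[2];
  G.hx = spacing[0]; G.hy = spacing[1]; G.hz = spacing[2];
  G.x1 = G.ox + G.hx * G.nx; G.y1 = G.oy + G.hy * G.ny;
  G.z1 = G.oz + G.hz * G.nz;
  int nr = nregions + 1; // slot 0 = void
  std::vector<double> sum(nr, 0.0), sumsq(nr, 0.0), hist(nr, 0.0);
  RNG rng((uint64_t)seed);
  int n = starts.nrow();
  double let = energy / range; // MeV per mm, constant
  for (int h = 0; h < n; ++h) {
    std::fill(hist.begin(), hist.end(), 0.0);
    double p[3] = {starts(h, 0), starts(h, 1), starts(h, 2)};
    double d[3];
    iso_dir(rng, d);
    double remaining = range;
    int guard = 0;
    while (remaining > 1e-12 && ++guard < 4000000) {
      // voxel of current position
      int i = (int)std::floor((p[0] - G.ox) / G.hx);
      int j = (int)std::floor((p[1] - G.oy) / G.hy);
      int k = (int)std::floor((p[2] - G.oz) / G.hz);
      if (i < 0 || j < 0 || k < 0 || i >= G.nx || j >= G.ny || k >= G.nz) {
        if (reflective) {
          reflect_fold(p[0], G.ox, G.x1, d[0]);
          reflect_fold(p[1], G.oy, G.y1, d[1]);
          reflect_fold(p[2], G.oz, G.z1, d[2]);
          continue;
        }
        break; // escapes: remaining energy lost
      }
      // distance to the next voxel face along d
      double tmin = remaining;
      if (d[0] > 1e-14) {
        double t = (G.ox + G.hx * (i + 1) - p[0]) / d[0];
        if (t < tmin) tmin = t;
      } else if (d[0] < -1e-14) {
        double t = (G.ox + G.hx * i - p[0]) / d[0];
        if (t < tmin) tmin = t;
      }
      if (d[1] > 1e-14) {
        double t = (G.oy + G.hy * (j + 1) - p[1]) / d[1];
        if (t < tmin) tmin = t;
      } else if (d[1] < -1e-14) {
        double t = (G.oy + G.hy * j - p[1]) / d[1];
        if (t < tmin) tmin = t;
      }
      if (d[2] > 1e-14) {
        double t = (G.oz + G.hz * (k + 1) - p[2]) / d[2];
        if (t < tmin) tmin = t;
      } else if (d[2] < -1e-14) {
        double t = (G.oz + G.hz * k - p[2]) / d[2];
        if (t < tmin) tmin = t;
      }
      if (tmin < 0) tmin = 0;
      // advance just past the voxel face; the nudge length is deposited in
      // the current voxel so the track energy is conserved exactly
      double adv = std::min(tmin, remaining) +
        1e-9 * std::min(std::min(G.hx, G.hy), G.hz);
      if (adv > remaining) adv = remaining;
      int lab = G.lab[i + (R_xlen_t)G.nx * (j + (R_xlen_t)G.ny * k)];
      hist[lab] += let * adv;
      remaining -= adv;
      p[0] += d[0] * adv; p[1] += d[1] * adv; p[2] += d[2] * adv;
    }
    for (int r = 0; r < nr; ++r) {
      sum[r] += hist[r];
      sumsq[r] += hist[r] * hist[r];
    }
  }
  NumericVector dep(nr), relerr(nr);
  for (int r = 0; r < nr; ++r) {
    dep[r] = sum[r];
    double mean = sum[r] / n;
    double var = sumsq[r] / n - mean * mean;
    if (var < 0) var = 0;
    relerr[r] = (mean > 0) ? std::sqrt(var / n) / mean : 0.0;
  }
  return List::create(_["deposit_MeV"] = dep, _["rel_err"] = relerr,
                      _["emitted_MeV"] = energy * (double)n,
                      _["histories"] = n);
}

// [[Rcpp::export(name = ".photon_transport")]]
List photon_transport(IntegerVector labels, IntegerVector dims,
                      NumericVector origin, NumericVector spacing,
                      NumericMatrix starts, double energy,
                      NumericVector mu_per_region, bool reflective,
                      double seed) {
  Grid G;
  G.lab = INTEGER(labels);
  G.nx = dims[0]; G.ny = dims[1]; G.nz = dims[2];
  G.ox = origin[0]; G.oy = origin[1]; G.oz = origin[2];
  G.hx = spacing[0]; G.hy = spacing[1]; G.hz = spacing[2];
  G.x1 = G.ox + G.hx * G.nx; G.y1 = G.oy + G.hy * G.ny;
  G.z1 = G.oz + G.hz * G.nz;
  int nr = mu_per_region.size(); // includes slot 0 = void (mu = 0)
  double mu_max = 0.0;
  for (int r = 0; r < nr; ++r) mu_max = std::max(mu_max, mu_per_region[r]);
  if (mu_max <= 0) stop("all attenuation coefficients are zero");
  std::vector<double> sum(nr, 0.0), sumsq(nr, 0.0);
  RNG rng((uint64_t)seed);
  int n = starts.nrow();
  for (int h = 0; h < n; ++h) {
    double p[3] = {starts(h, 0), starts(h, 1), starts(h, 2)};
    double d[3];
    iso_dir(rng, d);
    int dep_region = -1;
    int guard = 0;
    while (++guard < 2000000) {
      double s = -std::log(rng.unif()) / mu_max;
      p[0] += d[0] * s; p[1] += d[1] * s; p[2] += d[2] * s;
      if (p[0] < G.ox || p[0] > G.x1 || p[1] < G.oy || p[1] > G.y1 ||
          p[2] < G.oz || p[2] > G.z1) {
        if (reflective) {
          reflect_fold(p[0], G.ox, G.x1, d[0]);
          reflect_fold(p[1], G.oy, G.y1, d[1]);
          reflect_fold(p[2], G.oz, G.z1, d[2]);
        } else {
          break; // escapes
        }
      }
      int lab = G.region(p[0], p[1], p[2]);
      if (lab < 0) continue;
      if (rng.unif() < mu_per_region[lab] / mu_max) {
        dep_region = lab;
        break;
      }
    }
    for (int r = 0; r < nr; ++r) {
      double e = (r == dep_region) ? energy : 0.0;
      sum[r] += e;
      sumsq[r] += e * e;
    }
  }
  NumericVector dep(nr), relerr(nr);
  for (int r = 0; r < nr; ++r) {
    dep[r] = sum[r];
    double mean = sum[r] / n;
    double var = sumsq[r] / n - mean * mean;
    if (var < 0) var = 0;
    relerr[r] = (mean > 0) ? std::sqrt(var / n) / mean : 0.0;
  }
  return List::create(_["deposit_MeV"] = dep, _["rel_err"] = relerr,
                      _["emitted_MeV"] = energy * (double)n,
                      _["histories"] = n);
}
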