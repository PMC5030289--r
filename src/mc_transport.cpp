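// Voxelized Monte Carlo photon transport: launch, hop, drop, spin, roulette.
//
// The kernel walks weighted photon packets through a labeled voxel grid with
// per-medium (mu_a, mu_s, g). Free paths are sampled as optical depth and
// consumed voxel-by-voxel (step-through-voxel), so media changes along the
// path are handled exactly. Fluence is tallied with the track-length
// estimator (sum of W * pathlength per voxel); absorbed weight, escapes and
// roulette redistribution are accumulated in long double so the energy
// ledger closes to machine precision.
//
// RNG: xoshiro256++ seeded per photon index through splitmix64, so a given
// (seed, photon index) pair always sees the same stream regardless of
// execution order.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  void seed(uint64_t v) {
    uint64_t x = v;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    const uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }

  // uniform deviate strictly inside (0, 1)
  double unif() {
    return (static_cast<double>(next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

inline double hg_cos(double u, double g) {
  if (std::fabs(g) < 1e-6) return 2.0 * u - 1.0;
  const double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

}  // namespace

// [[Rcpp::export]]
List mc_propagate_cpp(IntegerVector labels, IntegerVector dim,
                      NumericVector vox_cm, NumericVector origin_cm,
                      NumericMatrix media, int source_kind, double src_x,
                      double src_y, double theta, double diameter_cm,
                      int gaussian_profile, double n_photons, double seed,
                      double w_threshold, double roulette_m) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double dx = vox_cm[0], dy = vox_cm[1], dz = vox_cm[2];
  const double x0 = origin_cm[0], y0 = origin_cm[1];
  const double xmax = x0 + nx * dx, ymax = y0 + ny * dy, zmax = nz * dz;
  const double nudge = 1e-9;  // cm, push past a voxel face
  const long N = static_cast<long>(n_photons);
  const uint64_t base_seed = static_cast<uint64_t>(seed);

  const int nm = media.nrow();
  std::vector<double> Ma(nm), Mg(nm), Mt(nm);
  for (int k = 0; k < nm; ++k) {
    Ma[k] = media(k, 0);
    Mg[k] = media(k, 2);
    Mt[k] = media(k, 0) + media(k, 1);
  }

  std::vector<double> flu(static_cast<size_t>(nx) * ny * nz, 0.0);
  std::vector<double> esc(static_cast<size_t>(nx) * ny, 0.0);

  long double absorbed = 0.0L, escaped_top = 0.0L, escaped_other = 0.0L;
  long double rr_killed = 0.0L, rr_gain = 0.0L;

  const double launch_ux = std::sin(theta);
  const double launch_uz = std::cos(theta);
  const long max_substeps = 20000000L;  // hard safety cap per photon

  for (long ip = 0; ip < N; ++ip) {
    Xoshiro rng;
    rng.seed(base_seed * 0x9E3779B97F4A7C15ULL + static_cast<uint64_t>(ip) + 1ULL);

    double x, y, z = 0.0;
    double ux = launch_ux, uy = 0.0, uz = launch_uz;
    double W = 1.0;

    if (source_kind == 0) {  // pencil
      x = src_x;
      y = src_y;
    } else if (source_kind == 1) {  // collimated disk
      double r;
      if (gaussian_profile) {
        // radial intensity ~ exp(-2 r^2 / w^2), w = 1/e^2 radius
        r = 0.5 * diameter_cm * std::sqrt(-std::log(rng.unif()) / 2.0);
      } else {
        r = 0.5 * diameter_cm * std::sqrt(rng.unif());
      }
      const double phi_l = 2.0 * M_PI * rng.unif();
      x = src_x + r * std::cos(phi_l);
      y = src_y + r * std::sin(phi_l);
    } else {  // plane wave over the whole top face
      x = x0 + rng.unif() * (xmax - x0);
      y = y0 + rng.unif() * (ymax - y0);
    }

    bool alive = true;
    long nsub = 0;

    while (alive) {
      double s = -std::log(rng.unif());  // dimensionless optical depth

      while (s > 0.0) {
        if (++nsub > max_substeps) {  // pathological trajectory: retire it
          rr_killed += W;
          alive = false;
          break;
        }
        if (x < x0 || x >= xmax || y < y0 || y >= ymax || z < 0.0 || z >= zmax) {
          if (z < 0.0 && uz < 0.0) {
            escaped_top += W;
            int ix = static_cast<int>((x - x0) / dx);
            int iy = static_cast<int>((y - y0) / dy);
            if (ix >= 0 && ix < nx && iy >= 0 && iy < ny)
              esc[static_cast<size_t>(ix) + static_cast<size_t>(nx) * iy] += W;
          } else {
            escaped_other += W;
          }
          alive = false;
          break;
        }

        const int ix = static_cast<int>((x - x0) / dx);
        const int iy = static_cast<int>((y - y0) / dy);
        const int iz = static_cast<int>(z / dz);
        const size_t idx = static_cast<size_t>(ix) +
                           static_cast<size_t>(nx) *
                               (static_cast<size_t>(iy) +
                                static_cast<size_t>(ny) * iz);
        const int lab = labels[idx] - 1;
        const double mua = Ma[lab];
        const double mut = Mt[lab];

        // distance to the nearest voxel face along the flight direction
        double db = 1e30, t;
        if (ux > 0.0) {
          t = ((x0 + (ix + 1) * dx) - x) / ux;
          if (t < db) db = t;
        } else if (ux < 0.0) {
          t = ((x0 + ix * dx) - x) / ux;
          if (t < db) db = t;
        }
        if (uy > 0.0) {
          t = ((y0 + (iy + 1) * dy) - y) / uy;
          if (t < db) db = t;
        } else if (uy < 0.0) {
          t = ((y0 + iy * dy) - y) / uy;
          if (t < db) db = t;
        }
        if (uz > 0.0) {
          t = ((iz + 1) * dz - z) / uz;
          if (t < db) db = t;
        } else if (uz < 0.0) {
          t = (iz * dz - z) / uz;
          if (t < db) db = t;
        }
        if (db < 0.0) db = 0.0;

        const double d = (mut > 0.0) ? s / mut : 1e30;

        if (d <= db) {
          // interaction inside this voxel
          x += d * ux;
          y += d * uy;
          z += d * uz;
          flu[idx] += W * d;
          s = 0.0;

          const double dw = W * mua / mut;
          absorbed += dw;
          W -= dw;

          const double cth = hg_cos(rng.unif(), Mg[lab]);
          const double sth = std::sqrt(1.0 - cth * cth);
          const double psi = 2.0 * M_PI * rng.unif();
          const double cp = std::cos(psi), sp = std::sin(psi);
          double nux, nuy, nuz;
          if (std::fabs(uz) > 0.99999) {
            nux = sth * cp;
            nuy = sth * sp;
            nuz = (uz >= 0.0) ? cth : -cth;
          } else {
            const double den = std::sqrt(1.0 - uz * uz);
            nux = sth * (ux * uz * cp - uy * sp) / den + ux * cth;
            nuy = sth * (uy * uz * cp + ux * sp) / den + uy * cth;
            nuz = -sth * cp * den + uz * cth;
          }
          const double nn = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
          ux = nux / nn;
          uy = nuy / nn;
          uz = nuz / nn;

          if (W < w_threshold) {
            if (rng.unif() * roulette_m < 1.0) {
              rr_gain += W * (roulette_m - 1.0);
              W *= roulette_m;
            } else {
              rr_killed += W;
              alive = false;
            }
          }
        } else {
          // cross into the next voxel
          const double step = db + nudge;
          x += step * ux;
          y += step * uy;
          z += step * uz;
          flu[idx] += W * db;
          if (mut > 0.0) s -= db * mut;
        }
      }
    }
  }

  NumericVector flu_out(flu.begin(), flu.end());
  NumericVector esc_out(esc.begin(), esc.end());

  return List::create(
      _["track_sum"] = flu_out, _["escape_sum"] = esc_out,
      _["absorbed"] = static_cast<double>(absorbed),
      _["escaped_top"] = static_cast<double>(escaped_top),
      _["escaped_other"] = static_cast<double>(escaped_other),
      _["roulette_killed"] = static_cast<double>(rr_killed),
      _["roulette_gain"] = static_cast<double>(rr_gain),
      _["n_photons"] = static_cast<double>(N));
}
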