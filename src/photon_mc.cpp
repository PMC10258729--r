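// White Monte Carlo photon transport in a homogeneous slab.
//
// Transport is simulated at zero absorption (mut = mus); absorption is
// applied afterwards by Beer-Lambert weighting of recorded path lengths.
// Geometry: slab of (xy half-widths hx, hy, thickness d), pencil beam
// normally incident at the origin of the top surface (z = 0, z grows into
// the medium). Top surface has a refractive-index mismatch against air
// (n_rel = n_medium / 1.0) handled by partial Fresnel transmission: at each
// top-boundary hit the transmitted fraction of the photon weight is
// recorded as an exit event (path length so far, exit radius, exit weight)
// and the reflected fraction continues. Bottom and side boundaries absorb.
//
// Determinism: a dedicated 64-bit Mersenne Twister seeded from R; the
// standardized mt19937_64 sequence makes runs reproducible across platforms
// (std::uniform_real_distribution is implementation-defined, so uniforms
// are built from raw 64-bit draws instead).

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

inline double runif53(std::mt19937_64& rng) {
  // uniform in [0, 1) with 53-bit resolution
  return (rng() >> 11) * (1.0 / 9007199254740992.0);
}

// unpolarized Fresnel reflectance for internal incidence, medium -> air
inline double fresnelR(double ci, double n_rel) {
  if (n_rel == 1.0) return 0.0;
  double si2 = 1.0 - ci * ci;
  double st2 = n_rel * n_rel * si2;       // Snell: n1 sin(ti) = n2 sin(tt), n2 = 1
  if (st2 >= 1.0) return 1.0;             // total internal reflection
  double ct = std::sqrt(1.0 - st2);
  double rs = (n_rel * ci - ct) / (n_rel * ci + ct);
  double rp = (ci - n_rel * ct) / (ci + n_rel * ct);
  return 0.5 * (rs * rs + rp * rp);
}

inline void spin(double& ux, double& uy, double& uz, double g,
                 std::mt19937_64& rng) {
  double ct;
  if (g == 0.0) {
    ct = 2.0 * runif53(rng) - 1.0;
  } else {
    double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * runif53(rng));
    ct = (1.0 + g * g - f * f) / (2.0 * g);
    if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
  }
  double st = std::sqrt(1.0 - ct * ct);
  double phi = 2.0 * M_PI * runif53(rng);
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nuz = -st * cp * den + uz * ct;
    double norm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
    ux = nux / norm; uy = nuy / norm; uz = nuz / norm;
  }
}

} // namespace

// [[Rcpp::export(name = ".mc_slab")]]
List mc_slab(double mus, double g, double n_rel,
             double hx, double hy, double depth,
             int n_photons, double max_path, double r_max,
             double w_min, double roulette_p, double seed) {
  if (n_photons < 1) stop("n_photons must be >= 1");
  if (mus <= 0) stop("mus must be > 0");

  std::mt19937_64 rng(static_cast<uint64_t>(seed));

  std::vector<double> out_L, out_r, out_w;
  out_L.reserve(4 * static_cast<size_t>(n_photons));
  out_r.reserve(4 * static_cast<size_t>(n_photons));
  out_w.reserve(4 * static_cast<size_t>(n_photons));

  double escaped_top = 0.0;   // recorded + unrecorded (r > r_max) exit weight
  double lost_other = 0.0;    // absorbed at bottom/side boundaries
  double lost_roulette = 0.0; // net weight destroyed (+) or created (-) by roulette
  double lost_cutoff = 0.0;   // terminated at the path-length cutoff

  // specular reflection at normal incidence on launch
  double rsp = (n_rel - 1.0) / (n_rel + 1.0);
  rsp = rsp * rsp;

  for (int ip = 0; ip < n_photons; ++ip) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0 - rsp;
    double L = 0.0;
    bool alive = true;

    while (alive) {
      double s = -std::log(1.0 - runif53(rng)) / mus;

      // propagate, handling boundary hits within the step
      while (s > 0.0) {
        double t = s;
        int hit = 0; // 1 top, 2 bottom, 3 side
        if (uz < 0.0) {
          double tb = -z / uz;
          if (tb < t) { t = tb; hit = 1; }
        } else if (uz > 0.0) {
          double tb = (depth - z) / uz;
          if (tb < t) { t = tb; hit = 2; }
        }
        if (ux > 0.0)      { double tb = (hx - x) / ux;  if (tb < t) { t = tb; hit = 3; } }
        else if (ux < 0.0) { double tb = (-hx - x) / ux; if (tb < t) { t = tb; hit = 3; } }
        if (uy > 0.0)      { double tb = (hy - y) / uy;  if (tb < t) { t = tb; hit = 3; } }
        else if (uy < 0.0) { double tb = (-hy - y) / uy; if (tb < t) { t = tb; hit = 3; } }

        x += t * ux; y += t * uy; z += t * uz;
        L += t;
        s -= t;

        if (hit == 0) break;
        if (hit == 2 || hit == 3) { lost_other += w; alive = false; break; }

        // top surface: record transmitted fraction, reflect the rest
        double ci = -uz;
        double R = fresnelR(ci, n_rel);
        if (R < 1.0) {
          double wt = w * (1.0 - R);
          escaped_top += wt;
          double r = std::sqrt(x * x + y * y);
          if (r <= r_max) {
            out_L.push_back(L);
            out_r.push_back(r);
            out_w.push_back(wt);
          }
          w *= R;
          if (w <= 0.0) { alive = false; break; }
        }
        uz = -uz;
        z = 0.0;
      }
      if (!alive) break;

      if (L > max_path) { lost_cutoff += w; break; }

      if (w < w_min) { // Russian roulette
        if (runif53(rng) < roulette_p) {
          lost_roulette -= w * (1.0 - roulette_p) / roulette_p;
          w /= roulette_p;
        } else {
          lost_roulette += w;
          break;
        }
      }

      spin(ux, uy, uz, g, rng);
    }
    if ((ip & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["path_mm"] = NumericVector(out_L.begin(), out_L.end()),
    _["radius_mm"] = NumericVector(out_r.begin(), out_r.end()),
    _["weight"] = NumericVector(out_w.begin(), out_w.end()),
    _["launched"] = static_cast<double>(n_photons),
    _["specular"] = rsp * n_photons,
    _["escaped_top"] = escaped_top,
    _["lost_other"] = lost_other,
    _["lost_roulette"] = lost_roulette,
    _["lost_cutoff"] = lost_cutoff);
}
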