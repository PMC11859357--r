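// Layered Monte Carlo photon transport with ring detectors.
//
// MCML-style weighted-photon transport: exponential step sampling,
// Henyey-Greenstein scattering, Fresnel events at every refractive-index
// mismatch, Russian roulette termination. Clear layers (mu_t == 0, e.g. a
// glass superstrate) are traversed with deterministic hops that do not
// consume the sampled dimensionless step. Photons exiting the top surface
// into the ambient medium deposit their weight in the ring whose annulus
// contains the exit radius; everything else is tallied so the weight budget
// closes per history (exactly when roulette is off, in expectation with
// roulette on).
//
// Reproducibility: each photon gets its own xoshiro256++ stream seeded by
// splitmix64 from (seed, photon index), so results are bit-identical for a
// fixed seed regardless of how the loop is batched.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256pp {
  uint64_t s[4];
  void seed(uint64_t x) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // uniform in (0, 1]; safe for log()
  inline double unif_pos() { return ((next() >> 11) + 1.0) * 0x1.0p-53; }
};

// Unpolarised Fresnel reflectance for a ray with |cos(incidence)| = ci
// crossing from index n1 into n2. Returns 1 beyond the critical angle and
// writes the transmitted |cos| into *ct_out otherwise.
inline double fresnel_R(double n1, double n2, double ci, double *ct_out) {
  if (n1 == n2) { *ct_out = ci; return 0.0; }
  if (ci > 1.0) ci = 1.0;
  const double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  const double st = n1 / n2 * si;
  if (st >= 1.0) { *ct_out = 0.0; return 1.0; }
  const double ct = std::sqrt(1.0 - st * st);
  *ct_out = ct;
  const double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  const double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

} // namespace

// mua_alt / mus_alt: optional perturbed coefficient sets (same length as
// mua). When non-empty, detected photons are additionally reweighted by the
// perturbation-MC likelihood ratio
//   prod_l (mus_alt/mus)^{j_l} * exp(-(mut_alt - mut) * L_l)
// (j_l collisions and path length L_l accumulated per layer), which
// estimates the detected weights under the perturbed coefficients from the
// same photon paths (exact correlation; unbiased up to roulette, whose
// trigger depends on the unperturbed weight).
// [[Rcpp::export]]
List mc_run_cpp(NumericVector mua, NumericVector mus, NumericVector g,
                NumericVector n_layer, NumericVector thickness,
                double n_above, double n_below,
                NumericVector ring_lo, NumericVector ring_hi,
                double n_photons, double seed,
                double roulette_threshold, double roulette_survival,
                bool roulette_on, double max_steps,
                Nullable<NumericVector> mua_alt_ = R_NilValue,
                Nullable<NumericVector> mus_alt_ = R_NilValue) {
  const int L = mua.size();
  const int R = ring_lo.size();
  if (mus.size() != L || g.size() != L || n_layer.size() != L ||
      thickness.size() != L)
    stop("layer property vectors must have equal length");
  for (int l = 0; l < L; ++l) {
    if (mua[l] < 0.0) stop("mu_a must be non-negative");
    if (mus[l] < 0.0) stop("mu_s must be non-negative");
    if (thickness[l] <= 0.0) stop("layer thickness must be positive");
    if (std::abs(g[l]) >= 1.0) stop("anisotropy g must lie in (-1, 1)");
  }

  const bool reweight = mua_alt_.isNotNull();
  NumericVector mua_alt, mus_alt;
  if (reweight) {
    if (mus_alt_.isNull())
      stop("both perturbed coefficient vectors are required");
    mua_alt = mua_alt_.get();
    mus_alt = mus_alt_.get();
    if (mua_alt.size() != L || mus_alt.size() != L)
      stop("perturbed coefficient vectors must match the layer count");
  }
  std::vector<double> log_mus_ratio(L, 0.0), dmut(L, 0.0);
  std::vector<bool> tagged(L, false);
  if (reweight)
    for (int l = 0; l < L; ++l) {
      if (mus_alt[l] != mus[l]) {
        if (mus[l] <= 0.0)
          stop("cannot reweight scattering in a non-scattering layer");
        log_mus_ratio[l] = std::log(mus_alt[l] / mus[l]);
      }
      dmut[l] = (mua_alt[l] + mus_alt[l]) - (mua[l] + mus[l]);
      tagged[l] = (mus_alt[l] != mus[l]) || (mua_alt[l] != mua[l]);
    }

  std::vector<double> z0(L), z1(L);
  double z = 0.0;
  for (int l = 0; l < L; ++l) { z0[l] = z; z += thickness[l]; z1[l] = z; }

  std::vector<double> det_w(R, 0.0), det_w2(R, 0.0);
  std::vector<double> det_w_alt(R, 0.0), det_w2_alt(R, 0.0);
  std::vector<double> absorbed(L, 0.0);
  double transmitted = 0.0, escaped = 0.0;
  std::vector<double> jcnt(L, 0.0), plen(L, 0.0);

  const uint64_t N = (uint64_t) n_photons;
  const uint64_t seed_u = (uint64_t) seed;
  Xoshiro256pp rng;

  for (uint64_t ip = 0; ip < N; ++ip) {
    rng.seed(seed_u * 0x9E3779B97F4A7C15ULL + ip);

    // Pencil beam, normal incidence on the top surface from the ambient
    // medium: the specular event is handled stochastically so every photon
    // carries unit weight into the budget.
    double ct0;
    const double Rspec = fresnel_R(n_above, n_layer[0], 1.0, &ct0);
    if (rng.unif() < Rspec) { escaped += 1.0; continue; }

    double x = 0.0, y = 0.0, pz = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0;
    int layer = 0;
    if (reweight) {
      std::fill(jcnt.begin(), jcnt.end(), 0.0);
      std::fill(plen.begin(), plen.end(), 0.0);
    }
    double sleft = 0.0;          // dimensionless remaining step
    bool alive = true;
    double steps = 0.0;

    while (alive) {
      if (++steps > max_steps) { absorbed[layer] += w; break; }
      const double mut = mua[layer] + mus[layer];
      if (sleft <= 0.0) sleft = -std::log(rng.unif_pos());

      // geometric distance to interaction (infinite in a clear layer)
      const double s_geo = (mut > 0.0) ? sleft / mut : R_PosInf;
      double d_bound = R_PosInf;
      if (uz > 0.0)      d_bound = (z1[layer] - pz) / uz;
      else if (uz < 0.0) d_bound = (z0[layer] - pz) / uz;
      if (!(d_bound < R_PosInf) && mut == 0.0) {
        // horizontal ray in a clear layer: measure-zero, drop conservatively
        absorbed[layer] += w;
        break;
      }

      if (d_bound <= s_geo) {
        // ---- boundary hit ----
        x += d_bound * ux; y += d_bound * uy;
        if (reweight && tagged[layer]) plen[layer] += d_bound;
        sleft -= d_bound * mut;
        if (sleft < 0.0) sleft = 0.0;
        const bool up = (uz < 0.0);
        pz = up ? z0[layer] : z1[layer];
        const double n1 = n_layer[layer];
        const double n2 = up ? (layer == 0 ? n_above : n_layer[layer - 1])
                             : (layer == L - 1 ? n_below : n_layer[layer + 1]);
        double ct;
        const double Rf = fresnel_R(n1, n2, std::fabs(uz), &ct);
        if (rng.unif() < Rf) {
          uz = -uz;              // reflected, stay in layer
        } else {
          const double scale = n1 / n2;
          ux *= scale; uy *= scale;
          uz = up ? -ct : ct;
          if (up && layer == 0) {
            // exits the top surface: detect or escape
            const double r = std::sqrt(x * x + y * y);
            int hit = -1;
            for (int k = 0; k < R; ++k)
              if (r >= ring_lo[k] && r < ring_hi[k]) { hit = k; break; }
            if (hit >= 0) {
              det_w[hit] += w; det_w2[hit] += w * w;
              if (reweight) {
                double lf = 0.0;
                for (int l = 0; l < L; ++l)
                  if (tagged[l])
                    lf += jcnt[l] * log_mus_ratio[l] - dmut[l] * plen[l];
                const double wa = w * std::exp(lf);
                det_w_alt[hit] += wa; det_w2_alt[hit] += wa * wa;
              }
            }
            else escaped += w;
            alive = false;
          } else if (!up && layer == L - 1) {
            transmitted += w;
            alive = false;
          } else {
            layer += up ? -1 : 1;
          }
        }
      } else {
        // ---- interaction ----
        x += s_geo * ux; y += s_geo * uy; pz += s_geo * uz;
        if (reweight && tagged[layer]) {
          plen[layer] += s_geo;
          jcnt[layer] += 1.0;
        }
        sleft = 0.0;
        const double dw = w * mua[layer] / mut;
        absorbed[layer] += dw;
        w -= dw;

        // Henyey-Greenstein deflection
        const double ga = g[layer];
        double cost;
        if (std::fabs(ga) < 1e-12) {
          cost = 2.0 * rng.unif() - 1.0;
        } else {
          const double tmp = (1.0 - ga * ga) / (1.0 - ga + 2.0 * ga * rng.unif());
          cost = (1.0 + ga * ga - tmp * tmp) / (2.0 * ga);
          if (cost > 1.0) cost = 1.0; else if (cost < -1.0) cost = -1.0;
        }
        const double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
        const double phi = 2.0 * M_PI * rng.unif();
        const double cosp = std::cos(phi), sinp = std::sin(phi);
        if (std::fabs(uz) > 0.99999) {
          ux = sint * cosp; uy = sint * sinp;
          uz = (uz >= 0.0) ? cost : -cost;
        } else {
          const double den = std::sqrt(1.0 - uz * uz);
          const double nux = sint * (ux * uz * cosp - uy * sinp) / den + ux * cost;
          const double nuy = sint * (uy * uz * cosp + ux * sinp) / den + uy * cost;
          const double nuz = -sint * cosp * den + uz * cost;
          ux = nux; uy = nuy; uz = nuz;
        }
        const double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
        ux /= norm; uy /= norm; uz /= norm;

        if (w < roulette_threshold) {
          if (roulette_on) {
            if (rng.unif() < roulette_survival) w /= roulette_survival;
            else alive = false;
          } else {
            // keep the per-history budget exact: bank the residual weight
            absorbed[layer] += w;
            alive = false;
          }
        }
      }
    }
  }

  List out = List::create(
    _["detected_w"] = NumericVector(det_w.begin(), det_w.end()),
    _["detected_w2"] = NumericVector(det_w2.begin(), det_w2.end()),
    _["absorbed"] = NumericVector(absorbed.begin(), absorbed.end()),
    _["transmitted"] = transmitted,
    _["escaped"] = escaped,
    _["n_photons"] = (double) N);
  if (reweight) {
    out["detected_w_alt"] = NumericVector(det_w_alt.begin(), det_w_alt.end());
    out["detected_w2_alt"] = NumericVector(det_w2_alt.begin(),
                                           det_w2_alt.end());
  }
  return out;
}
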