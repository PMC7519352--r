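#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic counter-free PRNG (xoshiro256++), seeded via splitmix64.
// Transport must be bit-reproducible for a given (seed, photon budget)
// independently of R's RNG state, so the engine carries its own generator.
// ---------------------------------------------------------------------------
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      // splitmix64
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1)
  inline double unif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  // uniform in (0, 1] (safe for log())
  inline double unif_pos() {
    return ((next() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
  inline double gauss() {
    // Box-Muller (one deviate per call; simple and adequate here)
    double u1 = unif_pos(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

// Unpolarized Fresnel reflectance for internal incidence, n_in -> n_out.
// ci = |cos(theta_i)| > 0.
static inline double fresnel_R(double n_in, double n_out, double ci) {
  double si2 = 1.0 - ci * ci;
  double st2 = (n_in / n_out) * (n_in / n_out) * si2;
  if (st2 >= 1.0) return 1.0;  // total internal reflection
  double ct = std::sqrt(1.0 - st2);
  double rs = (n_in * ci - n_out * ct) / (n_in * ci + n_out * ct);
  double rp = (n_in * ct - n_out * ci) / (n_in * ct + n_out * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein cos(theta) sample
static inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-8) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  return (1.0 + g * g - f * f) / (2.0 * g);
}

// Rotate direction (ux,uy,uz) by polar angle with cos ct, azimuth phi.
static inline void rotate_dir(double &ux, double &uy, double &uz,
                              double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz > 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nz = -st * cp * den + uz * ct;
    ux = nx; uy = ny; uz = nz;
  }
  double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= norm; uy /= norm; uz /= norm;
}

// ---------------------------------------------------------------------------
// Voxel Monte Carlo photon transport with track-length fluence estimation.
//
// Grid: nx x ny x nz isotropic voxels of size h (mm); x in [0, nx*h),
// y in [0, ny*h), z in [0, nz*h) with z = 0 the tissue surface. Photons
// crossing z = 0 upward undergo unpolarized Fresnel reflection/refraction
// against ambient n = 1; photons leaving through lateral or bottom faces
// are terminated and their weight booked as escaped (matched boundary).
// Optionally the y boundaries are periodic (used for y-invariant line
// kernels where the physical line source/detector is unbounded in y).
//
// launch_kind: 0 pencil (fixed pos, dir); 1 Gaussian line (x ~ N(x0, sigma),
// y ~ U(y0, y1), fixed dir); 2 cosine point (pos fixed, cosine-weighted
// downward hemisphere); 3 cosine line (x fixed, y ~ U, cosine hemisphere).
// entry_weight: initial photon weight (Fresnel transmittance applied by the
// caller at launch); 1 - entry_weight is booked as escaped (specular loss).
//
// Returns per-voxel fluence  sum(w * pathlength) / (n_photons * h^3)
// [mm^-2 per launched photon] plus an energy audit.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List mc_transport(IntegerVector dims, double h,
                  NumericVector mua, NumericVector mus,
                  NumericVector g, NumericVector nref,
                  int launch_kind, NumericVector launch_pos,
                  NumericVector launch_dir, double gauss_sigma,
                  NumericVector y_range, double entry_weight,
                  double n_photons, double seed,
                  bool periodic_y = false,
                  double cone_sin2 = 1.0,
                  double roulette_thresh = 1e-4,
                  double roulette_survive = 0.1) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double Lx = nx * h, Ly = ny * h, Lz = nz * h;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector flu(nvox);
  double *F = flu.begin();
  const double *MUA = mua.begin(), *MUS = mus.begin();
  const double *G = g.begin(), *NREF = nref.begin();
  const bool scalar_med = (mua.size() == 1);

  Xoshiro rng((uint64_t)seed + 0x51ab1ULL);
  const long N = (long)n_photons;
  double absorbed = 0.0, escaped = 0.0;
  escaped += (1.0 - entry_weight) * (double)N;  // specular loss at entry

  const double EPS = 1e-12;
  const long MAX_STEPS = 1000000L;

  for (long ip = 0; ip < N; ++ip) {
    // --- launch ---
    double x = launch_pos[0], y = launch_pos[1], z = launch_pos[2];
    double ux = launch_dir[0], uy = launch_dir[1], uz = launch_dir[2];
    if (launch_kind == 1 || launch_kind == 3) {
      y = y_range[0] + rng.unif() * (y_range[1] - y_range[0]);
      if (launch_kind == 1 && gauss_sigma > 0)
        x = launch_pos[0] + gauss_sigma * rng.gauss();
    }
    if (launch_kind == 2 || launch_kind == 3) {
      // cosine-weighted within the acceptance cone: uz^2 uniform in
      // [1 - cone_sin2, 1]; cone_sin2 = 1 is the full inward hemisphere
      double czen = std::sqrt(1.0 - rng.unif_pos() * cone_sin2);
      double phi = 2.0 * M_PI * rng.unif();
      double szen = std::sqrt(std::max(0.0, 1.0 - czen * czen));
      ux = szen * std::cos(phi);
      uy = szen * std::sin(phi);
      uz = czen;
    }
    if (x < 0 || x >= Lx || z < 0 || z >= Lz) { escaped += entry_weight; continue; }
    if (!periodic_y && (y < 0 || y >= Ly)) { escaped += entry_weight; continue; }
    if (periodic_y) {
      y -= Ly * std::floor(y / Ly);  // wrap into [0, Ly)
      if (y < 0 || y >= Ly) y = 0.0;
    }
    z = std::max(z, 0.0);
    double w = entry_weight;

    int ix = (int)(x / h), iy = (int)(y / h), iz = (int)(z / h);
    if (ix >= nx) ix = nx - 1;
    if (iy >= ny) iy = ny - 1;
    if (iz >= nz) iz = nz - 1;

    double tau = -std::log(rng.unif_pos());
    bool alive = true;
    long steps = 0;

    while (alive && ++steps < MAX_STEPS) {
      R_xlen_t idx = (R_xlen_t)ix + (R_xlen_t)nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz);
      double ma = scalar_med ? MUA[0] : MUA[idx];
      double ms = scalar_med ? MUS[0] : MUS[idx];
      double mt = ma + ms;
      // distance to the next voxel face along u
      double tx = (ux > EPS) ? (((ix + 1) * h - x) / ux)
                 : (ux < -EPS) ? ((ix * h - x) / ux) : 1e30;
      double ty = (uy > EPS) ? (((iy + 1) * h - y) / uy)
                 : (uy < -EPS) ? ((iy * h - y) / uy) : 1e30;
      double tz = (uz > EPS) ? (((iz + 1) * h - z) / uz)
                 : (uz < -EPS) ? ((iz * h - z) / uz) : 1e30;
      double tb = std::min(tx, std::min(ty, tz));
      if (tb < 0) tb = 0;

      bool interact = false;
      double s;
      if (mt > 0 && mt * tb >= tau) { s = tau / mt; interact = true; }
      else s = tb;

      F[idx] += w * s;                 // track-length deposit
      x += ux * s; y += uy * s; z += uz * s;

      if (interact) {
        absorbed += w * (ma / mt);
        if (ms <= 0) { alive = false; break; }  // pure absorber: terminate
        w *= ms / mt;
        double ct = hg_cos(scalar_med ? G[0] : G[idx], rng.unif());
        rotate_dir(ux, uy, uz, ct, 2.0 * M_PI * rng.unif());
        tau = -std::log(rng.unif_pos());
        // roulette
        if (w < roulette_thresh) {
          if (rng.unif() < roulette_survive) w /= roulette_survive;
          else { alive = false; break; }
        }
        continue;
      }

      // boundary crossing
      if (mt > 0) tau -= mt * tb;
      if (tb == tz) {
        if (uz < 0) {
          if (iz == 0) {
            // surface: Fresnel against ambient n = 1
            double nin = scalar_med ? NREF[0] : NREF[idx];
            double R = fresnel_R(nin, 1.0, -uz);
            if (rng.unif() < R) { uz = -uz; z = 0.0; }
            else { escaped += w; alive = false; }
          } else { iz--; z = (iz + 1) * h; }
        } else {
          if (iz == nz - 1) { escaped += w; alive = false; }
          else { iz++; z = iz * h; }
        }
      } else if (tb == tx) {
        if (ux < 0) {
          if (ix == 0) { escaped += w; alive = false; }
          else { ix--; x = (ix + 1) * h; }
        } else {
          if (ix == nx - 1) { escaped += w; alive = false; }
          else { ix++; x = ix * h; }
        }
      } else {
        if (uy < 0) {
          if (iy == 0) {
            if (periodic_y) { iy = ny - 1; y = Ly; }
            else { escaped += w; alive = false; }
          } else { iy--; y = (iy + 1) * h; }
        } else {
          if (iy == ny - 1) {
            if (periodic_y) { iy = 0; y = 0.0; }
            else { escaped += w; alive = false; }
          } else { iy++; y = iy * h; }
        }
      }
    }
  }

  double vol = h * h * h;
  for (R_xlen_t i = 0; i < nvox; ++i) F[i] /= ((double)N * vol);
  flu.attr("dim") = dims;
  return List::create(_["fluence"] = flu,
                      _["absorbed"] = absorbed,
                      _["escaped"] = escaped,
                      _["launched"] = (double)N,
                      _["audit"] = (absorbed + escaped) / (double)N);
}
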