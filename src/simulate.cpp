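// Brownian-dynamics photon-emission simulator.
//
// Particles diffuse freely in a periodic box centred on the laser focus;
// photon counts per time bin are Poisson with mean
//   dt * (background + brightness * sum_k PSF(r_k - r_focus))
// where the PSF is a peak-normalized 3D Gaussian ellipsoid.  The RNG is a
// self-contained xoshiro256++ stream seeded deterministically from the user
// seed, so traces are bit-reproducible and independent of R's RNG state.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }

  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on [0, 1)
  double runif() { return (next() >> 11) * 0x1.0p-53; }

  bool have_spare = false;
  double spare = 0.0;

  // standard normal, Marsaglia polar method
  double rnorm() {
    if (have_spare) {
      have_spare = false;
      return spare;
    }
    double u, v, q;
    do {
      u = 2.0 * runif() - 1.0;
      v = 2.0 * runif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    const double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    have_spare = true;
    return u * f;
  }

  // Poisson draw: Knuth inversion for small means, PTRS rejection otherwise
  int rpois(double lambda) {
    if (lambda <= 0.0) return 0;
    if (lambda < 10.0) {
      const double l = std::exp(-lambda);
      int k = 0;
      double p = 1.0;
      do {
        ++k;
        p *= runif();
      } while (p > l);
      return k - 1;
    }
    // PTRS (Hormann 1993, transformed rejection)
    const double b = 0.931 + 2.53 * std::sqrt(lambda);
    const double a = -0.059 + 0.02483 * b;
    const double inv_alpha = 1.1239 + 1.1328 / (b - 3.4);
    const double vr = 0.9277 - 3.6224 / (b - 2.0);
    for (;;) {
      double u = runif() - 0.5;
      double v = runif();
      double us = 0.5 - std::fabs(u);
      double k = std::floor((2.0 * a / us + b) * u + lambda + 0.43);
      if (us >= 0.07 && v <= vr) return (int)k;
      if (k < 0.0 || (us < 0.013 && v > us)) continue;
      if (std::log(v) + std::log(inv_alpha) - std::log(a / (us * us) + b) <=
          k * std::log(lambda) - lambda - std::lgamma(k + 1.0))
        return (int)k;
    }
  }
};

inline double wrap(double x, double L) {
  // periodic wrap into [-L/2, L/2)
  if (x >= -0.5 * L && x < 0.5 * L) return x;
  return x - L * std::floor(x / L + 0.5);
}

struct Psf {
  double cx, cy, cz;  // 2 / (s*w)^2 per axis
  Psf(double wx, double wy, double wz, double scale) {
    cx = 2.0 / (scale * wx * scale * wx);
    cy = 2.0 / (scale * wy * scale * wy);
    cz = 2.0 / (scale * wz * scale * wz);
  }
  // sum of peak-normalized Gaussian over particles at offset from focus
  double total(const std::vector<double> &x, const std::vector<double> &y,
               const std::vector<double> &z, double fx, double fy,
               double fz) const {
    double s = 0.0;
    const int n = (int)x.size();
    for (int k = 0; k < n; ++k) {
      const double dx = x[k] - fx;
      double q = cx * dx * dx;
      if (q > 34.5) continue;
      const double dy = y[k] - fy;
      q += cy * dy * dy;
      if (q > 34.5) continue;
      const double dz = z[k] - fz;
      q += cz * dz * dz;
      if (q > 34.5) continue;
      s += std::exp(-q);
    }
    return s;
  }
};

void init_positions(std::vector<double> &x, std::vector<double> &y,
                    std::vector<double> &z, int n, double Lx, double Ly,
                    double Lz, Xoshiro &rng, SEXP init) {
  x.resize(n);
  y.resize(n);
  z.resize(n);
  if (!Rf_isNull(init)) {
    NumericMatrix m(init);
    if (m.nrow() != n || m.ncol() != 3)
      stop("init_positions must be an n_particles x 3 matrix");
    for (int k = 0; k < n; ++k) {
      x[k] = m(k, 0);
      y[k] = m(k, 1);
      z[k] = m(k, 2);
    }
  } else {
    for (int k = 0; k < n; ++k) {
      x[k] = (rng.runif() - 0.5) * Lx;
      y[k] = (rng.runif() - 0.5) * Ly;
      z[k] = (rng.runif() - 0.5) * Lz;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List bd_simulate_fcs(int n_particles, NumericVector box, NumericVector dc,
                     double duration, double dt, double brightness,
                     double background, NumericVector waist, double psf_scale,
                     double seed, SEXP init, int traj_stride) {
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const R_xlen_t n_steps = (R_xlen_t)std::llround(duration / dt);
  if (n_steps < 1) stop("duration must cover at least one time step");
  if (n_steps > (R_xlen_t)2e9) stop("trace length exceeds addressable size");
  const double sx = std::sqrt(2.0 * dc[0] * dt);
  const double sy = std::sqrt(2.0 * dc[1] * dt);
  const double sz = std::sqrt(2.0 * dc[2] * dt);
  Psf psf(waist[0], waist[1], waist[2], psf_scale);
  Xoshiro rng((uint64_t)seed);

  std::vector<double> x, y, z;
  init_positions(x, y, z, n_particles, Lx, Ly, Lz, rng, init);
  // unwrapped copies for trajectory/MSD output
  std::vector<double> ux(x), uy(y), uz(z);
  const bool keep_traj = traj_stride > 0;
  R_xlen_t n_snap = keep_traj ? (n_steps / traj_stride + 1) : 0;
  NumericVector traj(keep_traj ? n_snap * n_particles * 3 : 0);
  R_xlen_t snap = 0;

  IntegerVector counts(n_steps);
  const bool diffuse = (sx > 0 || sy > 0 || sz > 0);
  for (R_xlen_t t = 0; t < n_steps; ++t) {
    if (keep_traj && t % traj_stride == 0) {
      for (int k = 0; k < n_particles; ++k) {
        traj[snap + n_snap * (0 + 3 * (R_xlen_t)k)] = ux[k];
        traj[snap + n_snap * (1 + 3 * (R_xlen_t)k)] = uy[k];
        traj[snap + n_snap * (2 + 3 * (R_xlen_t)k)] = uz[k];
      }
      ++snap;
    }
    const double rate =
        background + brightness * psf.total(x, y, z, 0.0, 0.0, 0.0);
    counts[t] = rng.rpois(rate * dt);
    if (diffuse) {
      for (int k = 0; k < n_particles; ++k) {
        const double ex = sx * rng.rnorm();
        const double ey = sy * rng.rnorm();
        const double ez = sz * rng.rnorm();
        ux[k] += ex;
        uy[k] += ey;
        uz[k] += ez;
        x[k] = wrap(x[k] + ex, Lx);
        y[k] = wrap(y[k] + ey, Ly);
        z[k] = wrap(z[k] + ez, Lz);
      }
    }
  }

  List out = List::create(Named("counts") = counts);
  if (keep_traj) {
    traj.attr("dim") =
        IntegerVector::create((int)n_snap, 3, n_particles);
    out["trajectories"] = traj;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector bd_simulate_rics(int n_particles, NumericVector box,
                               NumericVector dc, int n_frames, int n_rows,
                               int n_cols, double t_pix, double t_line,
                               double s_xi, double s_psi, double alpha_deg,
                               double brightness, double background,
                               NumericVector waist, double psf_scale,
                               double seed, SEXP init) {
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const double sx = std::sqrt(2.0 * dc[0] * t_pix);
  const double sy = std::sqrt(2.0 * dc[1] * t_pix);
  const double sz = std::sqrt(2.0 * dc[2] * t_pix);
  const double t_fly = t_line - n_cols * t_pix;
  if (t_fly < -1e-12) stop("t_line shorter than n_cols * t_pix");
  const double fx_s = std::sqrt(2.0 * dc[0] * std::max(t_fly, 0.0));
  const double fy_s = std::sqrt(2.0 * dc[1] * std::max(t_fly, 0.0));
  const double fz_s = std::sqrt(2.0 * dc[2] * std::max(t_fly, 0.0));
  const double ca = std::cos(alpha_deg * M_PI / 180.0);
  const double sa = std::sin(alpha_deg * M_PI / 180.0);
  Psf psf(waist[0], waist[1], waist[2], psf_scale);
  Xoshiro rng((uint64_t)seed);

  std::vector<double> x, y, z;
  init_positions(x, y, z, n_particles, Lx, Ly, Lz, rng, init);

  IntegerVector frames((R_xlen_t)n_frames * n_rows * n_cols);
  const bool diffuse = (dc[0] > 0 || dc[1] > 0 || dc[2] > 0);
  const double c0 = 0.5 * (n_cols - 1), r0 = 0.5 * (n_rows - 1);
  for (int f = 0; f < n_frames; ++f) {
    for (int j = 0; j < n_rows; ++j) {
      const double ys = (j - r0) * s_psi;
      for (int i = 0; i < n_cols; ++i) {
        const double xs = (i - c0) * s_xi;
        // scan coordinates rotated into the sample frame
        const double fx = ca * xs - sa * ys;
        const double fy = sa * xs + ca * ys;
        const double rate =
            background + brightness * psf.total(x, y, z, fx, fy, 0.0);
        frames[(R_xlen_t)f + (R_xlen_t)n_frames *
                                 (j + (R_xlen_t)n_rows * i)] =
            rng.rpois(rate * t_pix);
        if (diffuse) {
          for (int k = 0; k < n_particles; ++k) {
            x[k] = wrap(x[k] + sx * rng.rnorm(), Lx);
            y[k] = wrap(y[k] + sy * rng.rnorm(), Ly);
            z[k] = wrap(z[k] + sz * rng.rnorm(), Lz);
          }
        }
      }
      if (diffuse && t_fly > 0) {
        for (int k = 0; k < n_particles; ++k) {
          x[k] = wrap(x[k] + fx_s * rng.rnorm(), Lx);
          y[k] = wrap(y[k] + fy_s * rng.rnorm(), Ly);
          z[k] = wrap(z[k] + fz_s * rng.rnorm(), Lz);
        }
      }
    }
  }
  frames.attr("dim") = IntegerVector::create(n_frames, n_rows, n_cols);
  return frames;
}
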