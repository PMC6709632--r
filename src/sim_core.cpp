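#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Particle Monte Carlo engine for 2D membrane diffusion probed by Gaussian
// spots. One implementation serves free, trapped and hop modes; the R-level
// step_* helpers call it with n_steps = 1 so the physics exists once.
//
// Coordinates are centred on the origin: the square domain is
// [-L/2, L/2)^2 with periodic (minimum-image) wrapping; the circular domain
// has radius L/2 with antipodal re-entry (an exiting particle re-enters at
// the diametrically opposite boundary point, excess path carried inward).
//
// All randomness comes from R's RNG (RNGScope), so set.seed() upstream gives
// bit-reproducible trajectories.

namespace {

// Fast internal RNG for the hot loop: xoshiro256++ (Blackman & Vigna) with
// Marsaglia-polar Gaussians. Seeded from R's RNG at simulation start, so
// set.seed() upstream still fixes the whole trajectory bit-for-bit.
struct FastRng {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;

  void seed_from_R() {
    for (int i = 0; i < 4; ++i) {
      uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
      s[i] = (hi << 32) ^ lo;
    }
    if ((s[0] | s[1] | s[2] | s[3]) == 0) s[0] = 0x9E3779B97F4A7C15ULL;
    for (int i = 0; i < 16; ++i) next(); // warm up
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }

  inline double unif() { return (next() >> 11) * 0x1.0p-53; }

  inline double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    const double f = std::sqrt(-2.0 * std::log(s2) / s2);
    spare = v * f;
    have_spare = true;
    return u * f;
  }
};

inline double wrap1(double x, double L) {
  // map into [-L/2, L/2)
  double h = L / 2.0;
  double y = (x + h) / L;
  y -= std::floor(y);
  return y * L - h;
}

inline double min_image(double d, double L) {
  if (d > L / 2.0) d -= L;
  else if (d < -L / 2.0) d += L;
  return d;
}

// Nearest-seed (Voronoi cell) lookup over a bucket grid.
struct MeshIndex {
  int k = 0;
  int nb = 1;           // buckets per axis
  double L = 0, bw = 0; // domain side, bucket width
  bool periodic = true;
  std::vector<double> sx, sy;
  std::vector<double> r_safe;          // half distance to nearest other seed
  std::vector<std::vector<int> > bucket;

  void build(const NumericMatrix& seeds, double L_, bool periodic_) {
    k = seeds.nrow();
    L = L_;
    periodic = periodic_;
    sx.resize(k); sy.resize(k);
    for (int i = 0; i < k; ++i) { sx[i] = seeds(i, 0); sy[i] = seeds(i, 1); }
    nb = std::max(1, (int)std::floor(std::sqrt((double)k)));
    bw = L / nb;
    bucket.assign((size_t)nb * nb, std::vector<int>());
    for (int i = 0; i < k; ++i) bucket[bidx(sx[i], sy[i])].push_back(i);
    r_safe.assign(k, R_PosInf);
    for (int i = 0; i < k; ++i) {
      double best = R_PosInf;
      for (int j = 0; j < k; ++j) {
        if (j == i) continue;
        double dx = sx[i] - sx[j], dy = sy[i] - sy[j];
        if (periodic) { dx = min_image(dx, L); dy = min_image(dy, L); }
        double d2 = dx * dx + dy * dy;
        if (d2 < best) best = d2;
      }
      r_safe[i] = 0.5 * std::sqrt(best);
    }
  }

  inline int clampb(int b) const {
    if (periodic) { b %= nb; if (b < 0) b += nb; return b; }
    return std::min(std::max(b, 0), nb - 1);
  }

  inline size_t bidx(double x, double y) const {
    int bi = clampb((int)std::floor((x + L / 2.0) / bw));
    int bj = clampb((int)std::floor((y + L / 2.0) / bw));
    return (size_t)bj * nb + bi;
  }

  inline double dist2(double x, double y, int s) const {
    double dx = x - sx[s], dy = y - sy[s];
    if (periodic) { dx = min_image(dx, L); dy = min_image(dy, L); }
    return dx * dx + dy * dy;
  }

  // Exact nearest-seed lookup table on a fine raster: each raster cell
  // stores every seed that can be nearest to some point inside it (all
  // seeds within d_min(center) + h*sqrt(2) of the cell center), so a query
  // is a scan over a short (usually length-1) candidate list.
  int ng = 0;
  double h = 0;
  std::vector<int> cand_off, cand;

  void build_fine_grid() {
    ng = std::max(8, (int)std::ceil(L / (0.125 * L / std::sqrt((double)k)) /
                                    8.0) * 8);
    // target spacing ~ mesh/8; mesh ~ L/sqrt(k)
    ng = std::min(ng, 1024);
    h = L / ng;
    cand_off.assign((size_t)ng * ng + 1, 0);
    std::vector<std::vector<int> > lists((size_t)ng * ng);
    const double slack = h * M_SQRT2;
    for (int gj = 0; gj < ng; ++gj) {
      for (int gi = 0; gi < ng; ++gi) {
        double cx = -L / 2.0 + (gi + 0.5) * h;
        double cy = -L / 2.0 + (gj + 0.5) * h;
        int nb_seed = nearest(cx, cy);
        double dmin = std::sqrt(dist2(cx, cy, nb_seed));
        double rad2 = (dmin + slack) * (dmin + slack);
        std::vector<int>& lst = lists[(size_t)gj * ng + gi];
        for (int s = 0; s < k; ++s)
          if (dist2(cx, cy, s) <= rad2) lst.push_back(s);
      }
    }
    size_t tot = 0;
    for (size_t c = 0; c < lists.size(); ++c) {
      cand_off[c] = tot;
      tot += lists[c].size();
    }
    cand_off[lists.size()] = tot;
    cand.resize(tot);
    size_t pos = 0;
    for (size_t c = 0; c < lists.size(); ++c)
      for (size_t q = 0; q < lists[c].size(); ++q) cand[pos++] = lists[c][q];
  }

  inline int nearest_fast(double x, double y) const {
    int gi = (int)std::floor((x + L / 2.0) / h);
    int gj = (int)std::floor((y + L / 2.0) / h);
    if (gi < 0) gi = 0; else if (gi >= ng) gi = ng - 1;
    if (gj < 0) gj = 0; else if (gj >= ng) gj = ng - 1;
    size_t c = (size_t)gj * ng + gi;
    int best = cand[cand_off[c]];
    double best_d2 = dist2(x, y, best);
    for (size_t q = cand_off[c] + 1; q < (size_t)cand_off[c + 1]; ++q) {
      double d2 = dist2(x, y, cand[q]);
      if (d2 < best_d2) { best_d2 = d2; best = cand[q]; }
    }
    return best;
  }

  // exact nearest seed by expanding ring search
  int nearest(double x, double y) const {
    int bi = (int)std::floor((x + L / 2.0) / bw);
    int bj = (int)std::floor((y + L / 2.0) / bw);
    int best = -1;
    double best_d2 = R_PosInf;
    for (int r = 0; r <= nb; ++r) {
      // stop once no bucket in ring r can beat the current best:
      // any point in a ring-r bucket is at least (r-1)*bw away
      if (best >= 0) {
        double lb = (r - 1) * bw;
        if (lb > 0 && lb * lb > best_d2) break;
      }
      for (int di = -r; di <= r; ++di) {
        for (int dj = -r; dj <= r; ++dj) {
          if (std::max(std::abs(di), std::abs(dj)) != r) continue;
          int ci = clampb(bi + di), cj = clampb(bj + dj);
          const std::vector<int>& cell = bucket[(size_t)cj * nb + ci];
          for (size_t q = 0; q < cell.size(); ++q) {
            double d2 = dist2(x, y, cell[q]);
            if (d2 < best_d2) { best_d2 = d2; best = cell[q]; }
          }
        }
      }
      if (!periodic && r >= nb) break;
    }
    return best;
  }
};

} // namespace

// [[Rcpp::export]]
IntegerVector voronoi_cell_cpp(NumericMatrix points, NumericMatrix seeds,
                               double domain_size, bool periodic) {
  MeshIndex mi;
  mi.build(seeds, domain_size, periodic);
  int n = points.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = mi.nearest(points(i, 0), points(i, 1)) + 1; // 1-based for R
  return out;
}

// [[Rcpp::export]]
List sim_core(NumericMatrix pos0, NumericVector unwrapped0,
              LogicalVector trapped0, IntegerVector cell0,
              double D, double dt, int n_steps,
              double domain_size, int domain_shape, // 0 square torus, 1 circle
              int mode,                             // 0 free, 1 trapped, 2 hop
              double p_trap, double p_untrap, double p_hop,
              NumericMatrix seeds, NumericMatrix spots, double w0,
              int sample_stride, int traj_stride,
              bool poisson_noise, double counts_per_sample) {
  const int n = pos0.nrow();
  const int m = spots.nrow();
  const double L = domain_size;
  const double R = L / 2.0;
  const bool periodic = (domain_shape == 0);
  const double sigma = std::sqrt(2.0 * D * dt);
  const double w0sq = w0 * w0;
  const double r2cut = 9.0 * w0sq; // exp(-18) ~ 1.5e-8: negligible beyond 3 w0

  std::vector<double> x(n), y(n), ux(n), uy(n);
  std::vector<int> cell(n, -1);
  std::vector<char> trapped(n, 0);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1);
    ux[i] = unwrapped0[2 * i]; uy[i] = unwrapped0[2 * i + 1];
    trapped[i] = trapped0[i] ? 1 : 0;
  }

  FastRng rng;
  rng.seed_from_R();

  MeshIndex mi;
  if (mode == 2) {
    mi.build(seeds, L, periodic);
    mi.build_fine_grid();
    for (int i = 0; i < n; ++i) {
      cell[i] = (cell0.size() == n && cell0[i] > 0) ? cell0[i] - 1
                                                    : mi.nearest(x[i], y[i]);
      if (cell[i] < 0) stop("particle with undefined compartment id");
    }
  }

  const int n_samples = (sample_stride > 0) ? n_steps / sample_stride : 0;
  NumericMatrix intensity(std::max(n_samples, 0), m);
  IntegerVector n_trapped(std::max(n_samples, 0));

  const int n_rec = (traj_stride > 0) ? 1 + n_steps / traj_stride : 0;
  NumericVector traj(n_rec > 0 ? (R_xlen_t)n_rec * n * 2 : 0);
  NumericVector traj_t(std::max(n_rec, 0));
  int rec = 0;
  if (n_rec > 0) {
    for (int i = 0; i < n; ++i) {
      traj[(R_xlen_t)0 * n * 2 + i] = ux[i];
      traj[(R_xlen_t)0 * n * 2 + n + i] = uy[i];
    }
    traj_t[0] = 0.0;
    rec = 1;
  }

  int samp = 0;
  for (int step = 1; step <= n_steps; ++step) {
    // trap/untrap before displacement; a newly released particle moves now
    if (mode == 1) {
      // degenerate probabilities consume no draws, so p_trap = 0 reproduces
      // the free-mode trajectory bit-for-bit at the same seed
      for (int i = 0; i < n; ++i) {
        if (trapped[i]) {
          if (p_untrap > 0 && rng.unif() < p_untrap) trapped[i] = 0;
        } else if (p_trap > 0 && rng.unif() < p_trap) {
          trapped[i] = 1;
        }
      }
    }

    for (int i = 0; i < n; ++i) {
      if (trapped[i]) continue;
      double ddx = sigma * rng.norm();
      double ddy = sigma * rng.norm();
      double nx, ny;
      if (periodic) {
        nx = wrap1(x[i] + ddx, L);
        ny = wrap1(y[i] + ddy, L);
      } else {
        nx = x[i] + ddx; ny = y[i] + ddy;
        double r = std::sqrt(nx * nx + ny * ny);
        if (r > R) { // antipodal re-entry, excess carried inward
          double rn = 2.0 * R - r;
          if (rn < 0) rn = 0;
          nx = -nx / r * rn; ny = -ny / r * rn;
        }
      }
      if (mode == 2) {
        // quick same-cell test: inside the safe radius of the current seed
        double d2 = mi.dist2(nx, ny, cell[i]);
        double rs = mi.r_safe[cell[i]];
        if (d2 >= rs * rs) {
          int nc = mi.nearest_fast(nx, ny);
          if (nc != cell[i]) {
            if (rng.unif() < p_hop) cell[i] = nc;
            else continue; // bounce approximated by move rejection
          }
        }
      }
      x[i] = nx; y[i] = ny; ux[i] += ddx; uy[i] += ddy;
    }

    if (sample_stride > 0 && step % sample_stride == 0) {
      int ntr = 0;
      for (int i = 0; i < n; ++i) ntr += trapped[i];
      for (int s = 0; s < m; ++s) {
        double cx = spots(s, 0), cy = spots(s, 1);
        double acc = 0.0;
        for (int i = 0; i < n; ++i) {
          double dx = x[i] - cx, dy = y[i] - cy;
          if (periodic) { dx = min_image(dx, L); dy = min_image(dy, L); }
          double r2 = dx * dx + dy * dy;
          if (r2 < r2cut) acc += std::exp(-2.0 * r2 / w0sq);
        }
        if (poisson_noise) acc = R::rpois(acc * counts_per_sample);
        intensity(samp, s) = acc;
      }
      n_trapped[samp] = ntr;
      ++samp;
    }

    if (traj_stride > 0 && step % traj_stride == 0) {
      for (int i = 0; i < n; ++i) {
        traj[(R_xlen_t)rec * n * 2 + i] = ux[i];
        traj[(R_xlen_t)rec * n * 2 + n + i] = uy[i];
      }
      traj_t[rec] = step * dt;
      ++rec;
    }
  }

  NumericMatrix pos_out(n, 2), unw_out(n, 2);
  LogicalVector trap_out(n);
  IntegerVector cell_out(n);
  for (int i = 0; i < n; ++i) {
    pos_out(i, 0) = x[i]; pos_out(i, 1) = y[i];
    unw_out(i, 0) = ux[i]; unw_out(i, 1) = uy[i];
    trap_out[i] = trapped[i] != 0;
    cell_out[i] = (mode == 2) ? cell[i] + 1 : NA_INTEGER;
  }

  List out = List::create(
      _["intensity"] = intensity, _["n_trapped"] = n_trapped,
      _["positions"] = pos_out, _["unwrapped"] = unw_out,
      _["trapped"] = trap_out, _["cells"] = cell_out);
  if (n_rec > 0) {
    traj.attr("dim") = IntegerVector::create(n, 2, n_rec);
    out["traj"] = traj;
    out["traj_time"] = traj_t;
  }
  return out;
}
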