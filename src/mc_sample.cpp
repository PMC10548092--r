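#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Metropolis sampler for a beads-on-a-string chain at kT = 1.
// Coordinates are in units of the bond length a. Nonbonded beads interact
// through a spherical well of depth eps(i,j) on [hardcore, well); the hard
// core applies to every pair, the well is skipped for bonded neighbours
// (|i-j| == 1) whose geometry is fixed by the harmonic bond kb*(d - 1)^2.
// All randomness comes from R's RNG so set.seed() gives bit-identical runs.

static inline double sq(double x) { return x * x; }

struct Chain {
  int n;
  std::vector<double> x, y, z;
};

// energy of bead k against all others (bond + well), +Inf on hard-core hit
static double bead_energy(const Chain &c, int k, double px, double py, double pz,
                          const NumericMatrix &eps, double hc2, double well2,
                          double kb) {
  double e = 0.0;
  for (int j = 0; j < c.n; ++j) {
    if (j == k) continue;
    double d2 = sq(px - c.x[j]) + sq(py - c.y[j]) + sq(pz - c.z[j]);
    if (d2 < hc2) return R_PosInf;
    if (std::abs(j - k) == 1) {
      e += kb * sq(std::sqrt(d2) - 1.0);
    } else if (d2 < well2) {
      e += eps(k, j);
    }
  }
  return e;
}

// grow a random-walk chain with unit bonds avoiding the hard core
static bool init_chain(Chain &c, double hc2, int max_tries) {
  c.x[0] = c.y[0] = c.z[0] = 0.0;
  for (int i = 1; i < c.n; ++i) {
    bool placed = false;
    for (int t = 0; t < max_tries && !placed; ++t) {
      // uniform direction on the sphere
      double u = 2.0 * unif_rand() - 1.0;
      double phi = 2.0 * M_PI * unif_rand();
      double s = std::sqrt(std::max(0.0, 1.0 - u * u));
      double px = c.x[i - 1] + s * std::cos(phi);
      double py = c.y[i - 1] + s * std::sin(phi);
      double pz = c.z[i - 1] + u;
      placed = true;
      for (int j = 0; j < i; ++j) {
        double d2 = sq(px - c.x[j]) + sq(py - c.y[j]) + sq(pz - c.z[j]);
        if (d2 < hc2) { placed = false; break; }
      }
      if (placed) { c.x[i] = px; c.y[i] = py; c.z[i] = pz; }
    }
    if (!placed) return false;
  }
  return true;
}

// [[Rcpp::export(name = ".mc_sample_cpp")]]
List mc_sample_cpp(NumericMatrix eps, int n_structures, int burnin_sweeps,
                   int thin_sweeps, double hardcore, double well, double kb,
                   double sigma0, int max_segment) {
  const int n = eps.nrow();
  const double hc2 = hardcore * hardcore, well2 = well * well;
  Chain c;
  c.n = n;
  c.x.resize(n); c.y.resize(n); c.z.resize(n);

  bool ok = false;
  for (int r = 0; r < 50 && !ok; ++r) ok = init_chain(c, hc2, 200);
  if (!ok) stop("failed to construct a valid initial chain");

  double sigma = sigma0;
  long acc_disp = 0, try_disp = 0, acc_crank = 0, try_crank = 0;
  long tune_acc = 0, tune_try = 0;
  const bool can_crank = n >= 4 && max_segment >= 1;

  NumericVector coords(static_cast<R_xlen_t>(n_structures) * n * 3);
  int stored = 0;
  long total_sweeps = static_cast<long>(burnin_sweeps) +
                      static_cast<long>(thin_sweeps) * n_structures;
  std::vector<double> rx(n), ry(n), rz(n);

  for (long sweep = 0; sweep < total_sweeps; ++sweep) {
    for (int m = 0; m < n; ++m) {
      bool crank = can_crank && unif_rand() < 0.5;
      if (!crank) {
        ++try_disp; ++tune_try;
        int k = static_cast<int>(unif_rand() * n);
        if (k == n) k = n - 1;
        double px = c.x[k] + sigma * norm_rand();
        double py = c.y[k] + sigma * norm_rand();
        double pz = c.z[k] + sigma * norm_rand();
        double e_old = bead_energy(c, k, c.x[k], c.y[k], c.z[k], eps, hc2, well2, kb);
        double e_new = bead_energy(c, k, px, py, pz, eps, hc2, well2, kb);
        if (R_finite(e_new) &&
            (e_new <= e_old || unif_rand() < std::exp(e_old - e_new))) {
          c.x[k] = px; c.y[k] = py; c.z[k] = pz;
          ++acc_disp; ++tune_acc;
        }
      } else {
        ++try_crank;
        // rotate an internal segment about the axis through its flanking beads;
        // distances inside the segment and to the two axis beads are preserved,
        // so only segment-vs-exterior wells change
        int seg_max = std::min(max_segment, n - 2);
        int L = 1 + static_cast<int>(unif_rand() * seg_max);
        if (L > seg_max) L = seg_max;
        int i0 = static_cast<int>(unif_rand() * (n - L - 1));
        if (i0 > n - L - 2) i0 = n - L - 2;
        int i1 = i0 + L + 1; // fixed endpoints i0, i1
        double ax = c.x[i1] - c.x[i0], ay = c.y[i1] - c.y[i0], az = c.z[i1] - c.z[i0];
        double alen = std::sqrt(ax * ax + ay * ay + az * az);
        if (alen < 1e-12) continue;
        ax /= alen; ay /= alen; az /= alen;
        double th = (2.0 * unif_rand() - 1.0) * M_PI;
        double ct = std::cos(th), st = std::sin(th);
        bool reject = false;
        for (int k = i0 + 1; k < i1; ++k) {
          // Rodrigues rotation of (p - p_i0) about unit axis
          double vx = c.x[k] - c.x[i0], vy = c.y[k] - c.y[i0], vz = c.z[k] - c.z[i0];
          double dot = vx * ax + vy * ay + vz * az;
          double cx = ay * vz - az * vy, cy = az * vx - ax * vz, cz = ax * vy - ay * vx;
          rx[k] = c.x[i0] + vx * ct + cx * st + ax * dot * (1 - ct);
          ry[k] = c.y[i0] + vy * ct + cy * st + ay * dot * (1 - ct);
          rz[k] = c.z[i0] + vz * ct + cz * st + az * dot * (1 - ct);
        }
        double de = 0.0;
        for (int k = i0 + 1; k < i1 && !reject; ++k) {
          for (int j = 0; j < n; ++j) {
            if (j > i0 && j < i1) continue;       // internal: preserved
            double d2n = sq(rx[k] - c.x[j]) + sq(ry[k] - c.y[j]) + sq(rz[k] - c.z[j]);
            if (d2n < hc2) { reject = true; break; }
            if (j == i0 || j == i1) continue;     // on-axis: preserved
            double d2o = sq(c.x[k] - c.x[j]) + sq(c.y[k] - c.y[j]) + sq(c.z[k] - c.z[j]);
            if (std::abs(j - k) >= 2) {
              if (d2n < well2) de += eps(k, j);
              if (d2o < well2) de -= eps(k, j);
            }
          }
        }
        if (!reject && (de <= 0.0 || unif_rand() < std::exp(-de))) {
          for (int k = i0 + 1; k < i1; ++k) { c.x[k] = rx[k]; c.y[k] = ry[k]; c.z[k] = rz[k]; }
          ++acc_crank;
        }
      }
    }
    // adapt the displacement width over the first half of burn-in only,
    // so production sampling uses a fixed, detailed-balance-preserving kernel
    if (sweep < burnin_sweeps / 2 && tune_try >= 50L * n) {
      double rate = static_cast<double>(tune_acc) / tune_try;
      double f = rate / 0.4;
      if (f < 0.5) f = 0.5;
      if (f > 2.0) f = 2.0;
      sigma *= f;
      if (sigma < 0.02) sigma = 0.02;
      if (sigma > 2.0) sigma = 2.0;
      tune_acc = tune_try = 0;
    }
    if (sweep >= burnin_sweeps &&
        (sweep - burnin_sweeps + 1) % thin_sweeps == 0 && stored < n_structures) {
      for (int k = 0; k < n; ++k) {
        coords[stored + static_cast<R_xlen_t>(n_structures) * (0L * n + k)] = c.x[k];
        coords[stored + static_cast<R_xlen_t>(n_structures) * (1L * n + k)] = c.y[k];
        coords[stored + static_cast<R_xlen_t>(n_structures) * (2L * n + k)] = c.z[k];
      }
      ++stored;
    }
  }
  if (stored != n_structures) stop("internal error: stored %d of %d structures",
                                   stored, n_structures);
  coords.attr("dim") = IntegerVector::create(n_structures, n, 3);
  return List::create(
    _["coords"] = coords,
    _["accept_displacement"] = try_disp ? (double)acc_disp / try_disp : NA_REAL,
    _["accept_crankshaft"] = try_crank ? (double)acc_crank / try_crank : NA_REAL,
    _["sigma"] = sigma);
}

// contact frequency across an ensemble: entry (i,j) = fraction of
// conformations with d(i,j) < radius (strict); diagonal = 1
// [[Rcpp::export(name = ".contact_map_cpp")]]
NumericMatrix contact_map_cpp(NumericVector coords, double radius) {
  IntegerVector dim = coords.attr("dim");
  const int S = dim[0], n = dim[1];
  const double r2 = radius * radius;
  NumericMatrix out(n, n);
  for (int s = 0; s < S; ++s) {
    for (int i = 0; i < n; ++i) {
      double xi = coords[s + (R_xlen_t)S * (0L * n + i)];
      double yi = coords[s + (R_xlen_t)S * (1L * n + i)];
      double zi = coords[s + (R_xlen_t)S * (2L * n + i)];
      for (int j = i + 1; j < n; ++j) {
        double d2 = sq(xi - coords[s + (R_xlen_t)S * (0L * n + j)]) +
                    sq(yi - coords[s + (R_xlen_t)S * (1L * n + j)]) +
                    sq(zi - coords[s + (R_xlen_t)S * (2L * n + j)]);
        if (d2 < r2) { out(i, j) += 1.0; out(j, i) += 1.0; }
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    out(i, i) = 1.0;
    for (int j = 0; j < n; ++j) if (i != j) out(i, j) /= S;
  }
  return out;
}

// per-conformation pairwise distance matrix stack flattened to (S x npairs),
// pairs in column-major upper-triangle order; used by clustering and analyses
// [[Rcpp::export(name = ".pair_distances_cpp")]]
NumericMatrix pair_distances_cpp(NumericVector coords) {
  IntegerVector dim = coords.attr("dim");
  const int S = dim[0], n = dim[1];
  const int np = n * (n - 1) / 2;
  NumericMatrix out(S, np);
  for (int s = 0; s < S; ++s) {
    int col = 0;
    for (int j = 1; j < n; ++j) {
      for (int i = 0; i < j; ++i, ++col) {
        double d2 = sq(coords[s + (R_xlen_t)S * (0L * n + i)] - coords[s + (R_xlen_t)S * (0L * n + j)]) +
                    sq(coords[s + (R_xlen_t)S * (1L * n + i)] - coords[s + (R_xlen_t)S * (1L * n + j)]) +
                    sq(coords[s + (R_xlen_t)S * (2L * n + i)] - coords[s + (R_xlen_t)S * (2L * n + j)]);
        out(s, col) = std::sqrt(d2);
      }
    }
  }
  return out;
}
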