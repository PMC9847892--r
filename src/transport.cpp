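// Voxel-walking photon-packet Monte Carlo kernel.
//
// Geometry: labels[ix + nx*(iy + ny*iz)], isotropic voxels (mm); y (second
// axis) is depth, the outer surface faces -y. Optical coefficients are per
// cm; photon path lengths are accumulated in cm. Randomness comes from a
// self-contained counter-seeded generator, so a run is bit-reproducible
// from its integer seed alone.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Per-photon RNG substreams (xoroshiro128+ seeded via splitmix64). Each
// photon draws from its own stream derived from (run seed, photon index),
// so runs that differ only in optical coefficients keep photon-by-photon
// pairing: a packet whose history diverges (e.g. a shifted roulette
// decision) perturbs no other packet. This is what makes common-random-
// number comparisons across absorption scenarios effective.
static uint64_t rng_s[2];

static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline void rng_seed_photon(uint64_t run_seed, uint64_t photon) {
  uint64_t x = run_seed * 0x9E3779B97F4A7C15ULL + photon;
  rng_s[0] = splitmix64(x);
  rng_s[1] = splitmix64(x);
}

static inline uint64_t rotl64(uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

static inline uint64_t xnext() {
  uint64_t s0 = rng_s[0], s1 = rng_s[1];
  uint64_t r = s0 + s1;
  s1 ^= s0;
  rng_s[0] = rotl64(s0, 55) ^ s1 ^ (s1 << 14);
  rng_s[1] = rotl64(s1, 36);
  return r;
}

static inline double ru() {
  // uniform deviate strictly inside (0,1)
  double u;
  do { u = (xnext() >> 11) * 0x1.0p-53; } while (u <= 0.0 || u >= 1.0);
  return u;
}

static inline double hg_cos(double g, double xi) {
  if (std::fabs(g) < 1e-12) return 2.0 * xi - 1.0;
  double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * xi);
  double c = (1.0 + g * g - tmp * tmp) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// rotate unit vector u by deflection cos_t (polar) and phi (azimuth)
static inline void spin(double *u, double cos_t, double phi) {
  double sin_t = std::sqrt(std::max(0.0, 1.0 - cos_t * cos_t));
  double cp = std::cos(phi), sp = std::sin(phi);
  double ux = u[0], uy = u[1], uz = u[2];
  if (std::fabs(uz) > 0.99999) {
    u[0] = sin_t * cp;
    u[1] = sin_t * sp;
    u[2] = cos_t * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    u[0] = sin_t * (ux * uz * cp - uy * sp) / den + ux * cos_t;
    u[1] = sin_t * (uy * uz * cp + ux * sp) / den + uy * cos_t;
    u[2] = -sin_t * cp * den + uz * cos_t;
  }
  double nrm = std::sqrt(u[0]*u[0] + u[1]*u[1] + u[2]*u[2]);
  u[0] /= nrm; u[1] /= nrm; u[2] /= nrm;
}

// unpolarized Fresnel reflectance; cos_i in [0,1]
static inline double fresnel(double n1, double n2, double cos_i) {
  if (n1 == n2) return 0.0;
  if (cos_i > 0.99999) {
    double r = (n1 - n2) / (n1 + n2);
    return r * r;
  }
  double sin_i2 = 1.0 - cos_i * cos_i;
  double sin_t2 = (n1 / n2) * (n1 / n2) * sin_i2;
  if (sin_t2 >= 1.0) return 1.0;  // total internal reflection
  double cos_t = std::sqrt(1.0 - sin_t2);
  double rs = (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t);
  double rp = (n1 * cos_t - n2 * cos_i) / (n1 * cos_t + n2 * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

// [[Rcpp::export]]
double cpp_fresnel(double n1, double n2, double cos_i) {
  return fresnel(n1, n2, cos_i);
}

// [[Rcpp::export]]
double cpp_hg_cos(double g, double xi) { return hg_cos(g, xi); }

// [[Rcpp::export]]
NumericVector cpp_hg_direction(NumericVector dir, double g, double xi1,
                               double xi2) {
  double u[3] = {dir[0], dir[1], dir[2]};
  spin(u, hg_cos(g, xi1), 2.0 * M_PI * xi2);
  return NumericVector::create(u[0], u[1], u[2]);
}

// [[Rcpp::export]]
List mc_kernel(IntegerVector labels, IntegerVector dims, double voxel_mm,
               NumericVector prop_n, NumericVector prop_mua,
               NumericVector prop_mus, NumericVector prop_g,
               LogicalVector prop_valid, double ambient_n,
               double src_x, double src_z, int surface_iy,
               double det_x, double det_z, double det_half_mm,
               int n_photons, double roulette_thr, double roulette_p,
               bool record_all, bool tally_fluence,
               IntegerVector region_mask, int seed) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double v = voxel_mm;
  const int nlab = prop_n.size();
  const int *L = INTEGER(labels);
  const bool has_region = region_mask.size() > 0;
  const int *Rm = has_region ? INTEGER(region_mask) : nullptr;
  if (has_region && region_mask.size() != labels.size())
    stop("region mask does not match the volume");

  NumericVector A(nx * (R_xlen_t)ny * nz);
  NumericVector Tly(tally_fluence ? nx * (R_xlen_t)ny * nz : 0);
  double *Ap = REAL(A);
  double *Tp = tally_fluence ? REAL(Tly) : nullptr;

  // per-record columns: x,y,z, ux,uy,uz, weight, total_cm, partial per
  // label, partial within the optional focal region, photon index
  const int ncol = 8 + nlab + 2;
  std::vector<double> recs;
  std::vector<double> part(nlab);

  long double launched = 0.0L, specular = 0.0L, absorbed = 0.0L;
  long double exit_top = 0.0L, exit_bottom = 0.0L, exit_side = 0.0L;
  long double detected = 0.0L, killed = 0.0L, injected = 0.0L;

  // entry voxel
  int eix = (int)std::floor(src_x / v);
  int eiz = (int)std::floor(src_z / v);
  if (eix < 0 || eix >= nx || eiz < 0 || eiz >= nz ||
      surface_iy < 0 || surface_iy >= ny)
    stop("source position outside the volume");
  {
    int lab0 = L[eix + (R_xlen_t)nx * (surface_iy + (R_xlen_t)ny * eiz)];
    if (!prop_valid[lab0])
      stop("source entry voxel is air / unmapped (label %d)", lab0);
  }

  const double surf_y = surface_iy * v;

  for (int ph = 0; ph < n_photons; ++ph) {
    if ((ph & 0x3FF) == 0) Rcpp::checkUserInterrupt();
    rng_seed_photon((uint64_t)(uint32_t)seed, (uint64_t)ph);
    launched += 1.0L;
    double p[3] = {src_x, surf_y, src_z};
    double u[3] = {0.0, 1.0, 0.0};
    int ix = eix, iy = surface_iy, iz = eiz;
    int lab = L[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
    // specular entry reflection (normal incidence, ambient -> entry tissue)
    double rsp = fresnel(ambient_n, prop_n[lab], 1.0);
    double w = 1.0 - rsp;
    specular += rsp;

    std::fill(part.begin(), part.end(), 0.0);
    double part_reg = 0.0;
    double total_cm = 0.0;
    double tau = -std::log(ru());
    bool alive = true;
    long iter = 0;

    while (alive) {
      if (++iter > 50000000L) stop("photon exceeded iteration guard");
      lab = L[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
      if (!prop_valid[lab]) stop("unmapped label %d encountered", lab);
      double mut = prop_mua[lab] + prop_mus[lab];
      double s_mm = tau / mut * 10.0;

      // distance to the nearest voxel face along u
      double db = 1e30;
      int ax = -1, stp = 0;
      for (int a = 0; a < 3; ++a) {
        if (u[a] == 0.0) continue;
        int ia = (a == 0) ? ix : (a == 1) ? iy : iz;
        double face = (u[a] > 0.0) ? (ia + 1) * v : ia * v;
        double d = (face - p[a]) / u[a];
        if (d < 0.0) d = 0.0;
        if (d < db) { db = d; ax = a; stp = (u[a] > 0.0) ? 1 : -1; }
      }

      if (s_mm <= db) {
        // interaction inside the voxel
        for (int a = 0; a < 3; ++a) p[a] += u[a] * s_mm;
        double seg_cm = s_mm / 10.0;
        total_cm += seg_cm; part[lab] += seg_cm;
        R_xlen_t vidx = ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
        if (Rm && Rm[vidx]) part_reg += seg_cm;
        if (Tp) Tp[vidx] += w * seg_cm;
        double wnew = w * (prop_mus[lab] / mut);
        double dw = w - wnew;           // deposited fraction mua/mut
        Ap[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)] += dw;
        absorbed += dw;
        w = wnew;
        spin(u, hg_cos(prop_g[lab], ru()), 2.0 * M_PI * ru());
        tau = -std::log(ru());
        if (w < roulette_thr) {
          if (roulette_p >= 1.0) { /* roulette disabled */ }
          else if (ru() < roulette_p) {
            injected += (long double)w * (1.0 / roulette_p - 1.0);
            w /= roulette_p;
          } else {
            killed += w;
            alive = false;
          }
        }
        if (w <= 0.0) alive = false;
        continue;
      }

      // advance to the voxel face
      for (int a = 0; a < 3; ++a) p[a] += u[a] * db;
      double seg_cm = db / 10.0;
      total_cm += seg_cm; part[lab] += seg_cm;
      R_xlen_t vidx = ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
      if (Rm && Rm[vidx]) part_reg += seg_cm;
      if (Tp) Tp[vidx] += w * seg_cm;
      tau -= seg_cm * mut;
      if (tau < 0.0) tau = 0.0;

      int jx = ix, jy = iy, jz = iz;
      if (ax == 0) jx += stp; else if (ax == 1) jy += stp; else jz += stp;
      bool outside = (jx < 0 || jx >= nx || jy < 0 || jy >= ny ||
                      jz < 0 || jz >= nz);
      int nlabn = outside ? -1 :
        L[jx + (R_xlen_t)nx * (jy + (R_xlen_t)ny * jz)];
      bool to_air = outside || !prop_valid[nlabn];
      double n1 = prop_n[lab];
      double n2 = to_air ? ambient_n : prop_n[nlabn];

      if (n1 != n2) {
        double cos_i = std::fabs(u[ax]);
        double R = fresnel(n1, n2, cos_i);
        if (ru() < R) {           // internal reflection at the face
          u[ax] = -u[ax];
          continue;
        }
        // refract: scale tangential components, set normal component
        double sin_i2 = 1.0 - cos_i * cos_i;
        double sin_t2 = (n1 / n2) * (n1 / n2) * sin_i2;
        double cos_t = std::sqrt(std::max(0.0, 1.0 - sin_t2));
        for (int a = 0; a < 3; ++a)
          if (a != ax) u[a] *= n1 / n2;
        u[ax] = (u[ax] >= 0.0 ? 1.0 : -1.0) * cos_t;
        double nrm = std::sqrt(u[0]*u[0] + u[1]*u[1] + u[2]*u[2]);
        u[0] /= nrm; u[1] /= nrm; u[2] /= nrm;
      }

      if (to_air) {
        // photon leaves the tissue
        bool top = (ax == 1 && stp == -1);
        if (top) exit_top += w;
        else if (ax == 1) exit_bottom += w;
        else exit_side += w;
        bool in_det = top &&
          std::fabs(p[0] - det_x) <= det_half_mm &&
          std::fabs(p[2] - det_z) <= det_half_mm;
        if (in_det) detected += w;
        if (top && (record_all || in_det)) {
          recs.push_back(p[0]); recs.push_back(p[1]); recs.push_back(p[2]);
          recs.push_back(u[0]); recs.push_back(u[1]); recs.push_back(u[2]);
          recs.push_back(w); recs.push_back(total_cm);
          for (int k = 0; k < nlab; ++k) recs.push_back(part[k]);
          recs.push_back(part_reg);
          recs.push_back((double)ph);
        }
        alive = false;
        continue;
      }
      ix = jx; iy = jy; iz = jz;
    }
  }

  R_xlen_t nrec = (R_xlen_t)(recs.size() / ncol);
  NumericMatrix Rec(nrec, ncol);
  for (R_xlen_t i = 0; i < nrec; ++i)
    for (int j = 0; j < ncol; ++j)
      Rec(i, j) = recs[i * ncol + j];

  A.attr("dim") = dims;
  if (tally_fluence) Tly.attr("dim") = dims;

  return List::create(
    _["absorption"] = A,
    _["tally"] = tally_fluence ? (SEXP)Tly : R_NilValue,
    _["records"] = Rec,
    _["totals"] = NumericVector::create(
      _["launched"] = (double)launched,
      _["specular"] = (double)specular,
      _["absorbed"] = (double)absorbed,
      _["exit_top"] = (double)exit_top,
      _["exit_bottom"] = (double)exit_bottom,
      _["exit_side"] = (double)exit_side,
      _["detected"] = (double)detected,
      _["roulette_killed"] = (double)killed,
      _["roulette_injected"] = (double)injected));
}
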