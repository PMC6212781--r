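// Overdamped (Brownian) dynamics of a bead-spring chromatin fiber plus
// diffusing factor spheres.
//
// Force laws: harmonic bonds between consecutive beads; purely
// repulsive WCA excluded volume between all non-bonded pairs (soft
// core below 0.95 contact); a smooth half-cosine attractive well
// between a binding-competent factor and a bead it can bind (cognate
// color, or any bead when the species has a nonspecific affinity);
// optional Kratky-Porod bending; optional harmonic spherical
// confinement.  Units: nm, kT, Brownian times.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
#include "fast_rng.h"
using namespace Rcpp;

bool FastRng::tables_ready = false;
int64_t FastRng::kn[256];
double FastRng::wn[256], FastRng::fn[256];

static const double WCA_CUT = 1.122462048309373;  // 2^(1/6)
static const double CORE_CAP = 0.95;  // repulsion capped below 0.95*contact

struct Field {
  double kbond;         // kT/nm^2
  double r0;            // nm
  double eps_ev;        // kT
  double range_factor;  // attractive cutoff / contact distance
  double kappa;         // kT
  double Rconf;         // nm, <= 0 means unconfined
  double kconf;         // kT/nm^2
  double sigma_ref;     // bead diameter, stability reference
};

static Field read_field(const List& f) {
  Field fd;
  fd.kbond = as<double>(f["kbond"]);
  fd.r0 = as<double>(f["r0"]);
  fd.eps_ev = as<double>(f["eps_ev"]);
  fd.range_factor = as<double>(f["range_factor"]);
  fd.kappa = as<double>(f["kappa"]);
  fd.Rconf = as<double>(f["Rconf"]);
  fd.kconf = as<double>(f["kconf"]);
  fd.sigma_ref = as<double>(f["sigma_ref"]);
  return fd;
}

struct Sys {
  int n;  // beads
  int m;  // factors
  int N;  // n + m
  int K;  // palette size
  std::vector<double> x;        // 3N
  std::vector<double> diam;     // N
  std::vector<double> D;        // N, diffusion constants nm^2/tauB
  std::vector<int> beadcol;     // n*K, 0/1
  std::vector<int> fcol;        // m, 0-based, -1 = colorless
  std::vector<int> comp;        // m
  std::vector<double> eps_spec; // m
  std::vector<double> eps_ns;   // m
};

// attraction depth for pair (i, j); 0 means WCA-only
static inline double pair_eps_attr(const Sys& s, int i, int j) {
  int f = -1, b = -1;
  if (i >= s.n && j < s.n) { f = i - s.n; b = j; }
  else if (j >= s.n && i < s.n) { f = j - s.n; b = i; }
  else return 0.0;
  if (!s.comp[f]) return 0.0;
  int c = s.fcol[f];
  if (c >= 0 && s.beadcol[(size_t)b * s.K + c]) return s.eps_spec[f];
  return s.eps_ns[f];
}

// Repulsion: WCA core of strength eps_ev, force-capped below
// CORE_CAP * contact (linear soft core; the residual barrier to deep
// overlap is >100 kT, so the fiber stays effectively self-avoiding
// while single-step forces remain bounded).
// Attraction: a smooth half-cosine well, U = -eps for r <= contact,
// rising to 0 at the cutoff; its maximal force eps*pi/(2*(cutoff -
// contact)) is bounded, which keeps the overdamped update stable at
// the default timestep even for wells several kT deep.

// accumulate the non-bonded pair force between i and j into F
static inline void pair_force(const Sys& s, const Field& fd,
                              int i, int j, std::vector<double>& F) {
  double dx = s.x[3 * i] - s.x[3 * j];
  double dy = s.x[3 * i + 1] - s.x[3 * j + 1];
  double dz = s.x[3 * i + 2] - s.x[3 * j + 2];
  double r2 = dx * dx + dy * dy + dz * dz;
  double d = 0.5 * (s.diam[i] + s.diam[j]);
  double eps_a = pair_eps_attr(s, i, j);
  double cut = (eps_a > 0.0) ? fd.range_factor * d : WCA_CUT * d;
  if (r2 >= cut * cut) return;
  if (r2 < 1e-24) { dx = 1.0; dy = 0.0; dz = 0.0; r2 = 1e-24; }
  double r = std::sqrt(r2);
  double fr = 0.0;  // F / r along (xi - xj)
  // WCA core
  if (fd.eps_ev > 0.0 && r < WCA_CUT * d) {
    double rcap = CORE_CAP * d;
    double re = r < rcap ? rcap : r;
    double s2 = d * d / (re * re);
    double s6 = s2 * s2 * s2;
    fr += 24.0 * fd.eps_ev * s6 * (2.0 * s6 - 1.0) / (re * re) *
          (re / r);  // capped magnitude, true direction
  }
  // attractive well
  if (eps_a > 0.0 && r > d) {
    double w = cut - d;
    double arg = M_PI * (r - d) / w;
    fr += -eps_a * M_PI / (2.0 * w) * std::sin(arg) / r;
  }
  F[3 * i] += fr * dx; F[3 * i + 1] += fr * dy; F[3 * i + 2] += fr * dz;
  F[3 * j] -= fr * dx; F[3 * j + 1] -= fr * dy; F[3 * j + 2] -= fr * dz;
}

static inline double pair_energy(const Sys& s, const Field& fd,
                                 int i, int j) {
  double dx = s.x[3 * i] - s.x[3 * j];
  double dy = s.x[3 * i + 1] - s.x[3 * j + 1];
  double dz = s.x[3 * i + 2] - s.x[3 * j + 2];
  double r2 = dx * dx + dy * dy + dz * dz;
  double d = 0.5 * (s.diam[i] + s.diam[j]);
  double eps_a = pair_eps_attr(s, i, j);
  double cut = (eps_a > 0.0) ? fd.range_factor * d : WCA_CUT * d;
  if (r2 >= cut * cut) return 0.0;
  double r = std::sqrt(r2);
  double u = 0.0;
  if (fd.eps_ev > 0.0 && r < WCA_CUT * d) {
    double rcap = CORE_CAP * d;
    double re = r < rcap ? rcap : r;
    double s2 = d * d / (re * re);
    double s6 = s2 * s2 * s2;
    u += 4.0 * fd.eps_ev * s6 * (s6 - 1.0) + fd.eps_ev;
    if (r < rcap) {  // linear continuation of the capped core
      double fcap = 24.0 * fd.eps_ev * s6 * (2.0 * s6 - 1.0) / re;
      u += fcap * (rcap - r);
    }
  }
  if (eps_a > 0.0) {
    if (r <= d) u += -eps_a;
    else {
      double w = cut - d;
      u += -0.5 * eps_a * (1.0 + std::cos(M_PI * (r - d) / w));
    }
  }
  return u;
}

// bonds + bending + confinement; returns energy if want_energy
static double bonded_forces(const Sys& s, const Field& fd,
                            std::vector<double>* F, bool want_energy) {
  double U = 0.0;
  // harmonic bonds between consecutive beads
  for (int i = 0; i + 1 < s.n; ++i) {
    double dx = s.x[3 * i] - s.x[3 * (i + 1)];
    double dy = s.x[3 * i + 1] - s.x[3 * (i + 1) + 1];
    double dz = s.x[3 * i + 2] - s.x[3 * (i + 1) + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (want_energy) U += 0.5 * fd.kbond * (r - fd.r0) * (r - fd.r0);
    if (F && r > 1e-12) {
      double fr = -fd.kbond * (r - fd.r0) / r;
      (*F)[3 * i] += fr * dx; (*F)[3 * i + 1] += fr * dy;
      (*F)[3 * i + 2] += fr * dz;
      (*F)[3 * (i + 1)] -= fr * dx; (*F)[3 * (i + 1) + 1] -= fr * dy;
      (*F)[3 * (i + 1) + 2] -= fr * dz;
    }
  }
  // Kratky-Porod bending on bead triples
  if (fd.kappa > 0.0) {
    for (int i = 1; i + 1 < s.n; ++i) {
      double ux = s.x[3 * i] - s.x[3 * (i - 1)];
      double uy = s.x[3 * i + 1] - s.x[3 * (i - 1) + 1];
      double uz = s.x[3 * i + 2] - s.x[3 * (i - 1) + 2];
      double vx = s.x[3 * (i + 1)] - s.x[3 * i];
      double vy = s.x[3 * (i + 1) + 1] - s.x[3 * i + 1];
      double vz = s.x[3 * (i + 1) + 2] - s.x[3 * i + 2];
      double lu = std::sqrt(ux * ux + uy * uy + uz * uz);
      double lv = std::sqrt(vx * vx + vy * vy + vz * vz);
      if (lu < 1e-12 || lv < 1e-12) continue;
      double c = (ux * vx + uy * vy + uz * vz) / (lu * lv);
      if (c > 1.0) c = 1.0; if (c < -1.0) c = -1.0;
      if (want_energy) U += fd.kappa * (1.0 - c);
      if (F) {
        double ax = vx / (lu * lv) - c * ux / (lu * lu);
        double ay = vy / (lu * lv) - c * uy / (lu * lu);
        double az = vz / (lu * lv) - c * uz / (lu * lu);
        double bx = ux / (lu * lv) - c * vx / (lv * lv);
        double by = uy / (lu * lv) - c * vy / (lv * lv);
        double bz = uz / (lu * lv) - c * vz / (lv * lv);
        // F = -dU/dr = kappa * dc/dr
        (*F)[3 * (i - 1)] += -fd.kappa * ax;
        (*F)[3 * (i - 1) + 1] += -fd.kappa * ay;
        (*F)[3 * (i - 1) + 2] += -fd.kappa * az;
        (*F)[3 * (i + 1)] += fd.kappa * bx;
        (*F)[3 * (i + 1) + 1] += fd.kappa * by;
        (*F)[3 * (i + 1) + 2] += fd.kappa * bz;
        (*F)[3 * i] += fd.kappa * (ax - bx);
        (*F)[3 * i + 1] += fd.kappa * (ay - by);
        (*F)[3 * i + 2] += fd.kappa * (az - bz);
      }
    }
  }
  // spherical confinement
  if (fd.Rconf > 0.0) {
    for (int i = 0; i < s.N; ++i) {
      double rx = s.x[3 * i], ry = s.x[3 * i + 1], rz = s.x[3 * i + 2];
      double r = std::sqrt(rx * rx + ry * ry + rz * rz);
      double e = r + 0.5 * s.diam[i] - fd.Rconf;
      if (e > 0.0 && r > 1e-12) {
        if (want_energy) U += 0.5 * fd.kconf * e * e;
        if (F) {
          double fr = -fd.kconf * e / r;
          (*F)[3 * i] += fr * rx; (*F)[3 * i + 1] += fr * ry;
          (*F)[3 * i + 2] += fr * rz;
        }
      }
    }
  }
  return U;
}

static Sys build_sys(const NumericMatrix& pos, int n_beads,
                     const IntegerMatrix& beadcol,
                     const IntegerVector& fcol,
                     const LogicalVector& comp,
                     const NumericVector& diam,
                     const NumericVector& D,
                     const NumericVector& eps_spec,
                     const NumericVector& eps_ns) {
  Sys s;
  s.N = pos.nrow();
  s.n = n_beads;
  s.m = s.N - s.n;
  s.K = beadcol.ncol();
  s.x.resize(3 * s.N);
  for (int i = 0; i < s.N; ++i) {
    s.x[3 * i] = pos(i, 0); s.x[3 * i + 1] = pos(i, 1);
    s.x[3 * i + 2] = pos(i, 2);
  }
  s.diam.assign(diam.begin(), diam.end());
  s.D.assign(D.begin(), D.end());
  s.beadcol.resize((size_t)s.n * s.K);
  for (int i = 0; i < s.n; ++i)
    for (int k = 0; k < s.K; ++k)
      s.beadcol[(size_t)i * s.K + k] = beadcol(i, k);
  s.fcol.assign(fcol.begin(), fcol.end());
  s.comp.assign(comp.begin(), comp.end());
  s.eps_spec.assign(eps_spec.begin(), eps_spec.end());
  s.eps_ns.assign(eps_ns.begin(), eps_ns.end());
  return s;
}

// ---- Verlet/cell neighbor list ------------------------------------------

struct NeighborList {
  std::vector<int> pi, pj;        // pair lists (i < j)
  std::vector<double> x_build;    // positions at build time
  double skin;
  double cut_bb, cut_fb, cut_ff;  // interaction cutoffs by pair type
  int n_rebuilds = 0;

  void build(const Sys& s) {
    pi.clear(); pj.clear();
    x_build = s.x;
    double rlist_max = std::max(cut_fb, std::max(cut_bb, cut_ff)) + skin;
    // bounding box
    double lo[3], hi[3];
    for (int c = 0; c < 3; ++c) { lo[c] = 1e300; hi[c] = -1e300; }
    for (int i = 0; i < s.N; ++i)
      for (int c = 0; c < 3; ++c) {
        if (s.x[3 * i + c] < lo[c]) lo[c] = s.x[3 * i + c];
        if (s.x[3 * i + c] > hi[c]) hi[c] = s.x[3 * i + c];
      }
    int nc[3];
    for (int c = 0; c < 3; ++c) {
      nc[c] = std::max(1, (int)std::floor((hi[c] - lo[c]) / rlist_max));
      if (nc[c] > 64) nc[c] = 64;
    }
    double cw[3];
    for (int c = 0; c < 3; ++c)
      cw[c] = std::max((hi[c] - lo[c]) / nc[c], rlist_max);
    int ncell = nc[0] * nc[1] * nc[2];
    std::vector<int> head(ncell, -1), nxt(s.N, -1), cellof(s.N);
    for (int i = 0; i < s.N; ++i) {
      int ix = std::min(nc[0] - 1,
                        (int)((s.x[3 * i] - lo[0]) / cw[0]));
      int iy = std::min(nc[1] - 1,
                        (int)((s.x[3 * i + 1] - lo[1]) / cw[1]));
      int iz = std::min(nc[2] - 1,
                        (int)((s.x[3 * i + 2] - lo[2]) / cw[2]));
      int cid = (ix * nc[1] + iy) * nc[2] + iz;
      cellof[i] = cid;
      nxt[i] = head[cid]; head[cid] = i;
    }
    for (int ix = 0; ix < nc[0]; ++ix)
      for (int iy = 0; iy < nc[1]; ++iy)
        for (int iz = 0; iz < nc[2]; ++iz) {
          int cid = (ix * nc[1] + iy) * nc[2] + iz;
          for (int dx = -1; dx <= 1; ++dx)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dz = -1; dz <= 1; ++dz) {
                int jx = ix + dx, jy = iy + dy, jz = iz + dz;
                if (jx < 0 || jx >= nc[0] || jy < 0 || jy >= nc[1] ||
                    jz < 0 || jz >= nc[2]) continue;
                int cjd = (jx * nc[1] + jy) * nc[2] + jz;
                if (cjd < cid) continue;
                for (int a = head[cid]; a >= 0; a = nxt[a])
                  for (int b = (cjd == cid ? nxt[a] : head[cjd]);
                       b >= 0; b = nxt[b])
                    consider(s, a, b);
              }
        }
    ++n_rebuilds;
  }

  inline void consider(const Sys& s, int a, int b) {
    int i = a < b ? a : b, j = a < b ? b : a;
    bool ib = i < s.n, jb = j < s.n;
    if (ib && jb && j == i + 1) return;  // bonded pair handled separately
    double rl;
    if (ib && jb) rl = cut_bb + skin;
    else if (!ib && !jb) rl = cut_ff + skin;
    else rl = cut_fb + skin;
    double dx = s.x[3 * i] - s.x[3 * j];
    double dy = s.x[3 * i + 1] - s.x[3 * j + 1];
    double dz = s.x[3 * i + 2] - s.x[3 * j + 2];
    if (dx * dx + dy * dy + dz * dz < rl * rl) { pi.push_back(i); pj.push_back(j); }
  }

  bool needs_rebuild(const Sys& s) const {
    double m1 = 0.0, m2 = 0.0;  // two largest displacements
    for (int i = 0; i < s.N; ++i) {
      double dx = s.x[3 * i] - x_build[3 * i];
      double dy = s.x[3 * i + 1] - x_build[3 * i + 1];
      double dz = s.x[3 * i + 2] - x_build[3 * i + 2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > m1) { m2 = m1; m1 = d2; }
      else if (d2 > m2) m2 = d2;
    }
    return std::sqrt(m1) + std::sqrt(m2) > skin;
  }
};

// ---- exported single-shot evaluators ------------------------------------

// [[Rcpp::export]]
NumericMatrix engine_forces(NumericMatrix pos, int n_beads,
                            IntegerMatrix beadcol, IntegerVector fcol,
                            LogicalVector comp, NumericVector diam,
                            NumericVector D, NumericVector eps_spec,
                            NumericVector eps_ns, List field) {
  Sys s = build_sys(pos, n_beads, beadcol, fcol, comp, diam, D,
                    eps_spec, eps_ns);
  Field fd = read_field(field);
  std::vector<double> F(3 * s.N, 0.0);
  for (int i = 0; i < s.N; ++i)
    for (int j = i + 1; j < s.N; ++j) {
      if (i < s.n && j < s.n && j == i + 1) continue;
      pair_force(s, fd, i, j, F);
    }
  bonded_forces(s, fd, &F, false);
  NumericMatrix out(s.N, 3);
  for (int i = 0; i < s.N; ++i) {
    out(i, 0) = F[3 * i]; out(i, 1) = F[3 * i + 1]; out(i, 2) = F[3 * i + 2];
  }
  return out;
}

// [[Rcpp::export]]
double engine_energy(NumericMatrix pos, int n_beads,
                     IntegerMatrix beadcol, IntegerVector fcol,
                     LogicalVector comp, NumericVector diam,
                     NumericVector D, NumericVector eps_spec,
                     NumericVector eps_ns, List field) {
  Sys s = build_sys(pos, n_beads, beadcol, fcol, comp, diam, D,
                    eps_spec, eps_ns);
  Field fd = read_field(field);
  double U = 0.0;
  for (int i = 0; i < s.N; ++i)
    for (int j = i + 1; j < s.N; ++j) {
      if (i < s.n && j < s.n && j == i + 1) continue;
      U += pair_energy(s, fd, i, j);
    }
  U += bonded_forces(s, fd, nullptr, true);
  return U;
}

// ---- the main integrator ------------------------------------------------

// [[Rcpp::export]]
List engine_run(NumericMatrix pos, int n_beads, IntegerMatrix beadcol,
                IntegerVector fcol, LogicalVector comp0,
                NumericVector diam, NumericVector D,
                NumericVector eps_spec, NumericVector eps_ns,
                NumericVector koff, NumericVector kon, List field,
                double dt, int n_steps, int equil, int frame_every,
                bool noise, bool pin_beads) {
  Sys s = build_sys(pos, n_beads, beadcol, fcol, comp0, diam, D,
                    eps_spec, eps_ns);
  Field fd = read_field(field);
  if (dt < 0) stop("dt must be non-negative");

  double dmax_bead = 0.0, dmax_fac = 0.0, dmax_all = 0.0;
  for (int i = 0; i < s.N; ++i) {
    dmax_all = std::max(dmax_all, s.diam[i]);
    if (i < s.n) dmax_bead = std::max(dmax_bead, s.diam[i]);
    else dmax_fac = std::max(dmax_fac, s.diam[i]);
  }
  NeighborList nl;
  nl.skin = 1.0 * fd.sigma_ref;
  nl.cut_bb = WCA_CUT * dmax_bead;
  nl.cut_ff = WCA_CUT * dmax_fac;
  nl.cut_fb = fd.range_factor * 0.5 * (dmax_bead + dmax_fac);
  bool any_ns = false;
  for (double e : s.eps_ns) if (e > 0) any_ns = true;
  bool any_spec = s.m > 0;
  if (!any_spec) nl.cut_fb = nl.cut_ff;

  bool any_switch = false;
  for (int f = 0; f < s.m; ++f)
    if (koff[f] > 0 || kon[f] > 0) any_switch = true;
  (void)any_ns;

  int nframes = frame_every > 0 ? (n_steps - equil) / frame_every : 0;
  NumericVector times(std::max(nframes, 0));
  List frames(std::max(nframes, 0));
  List comps(std::max(nframes, 0));

  std::vector<double> F(3 * s.N);
  std::vector<double> sq2Ddt(s.N);
  for (int i = 0; i < s.N; ++i)
    sq2Ddt[i] = std::sqrt(2.0 * s.D[i] * dt);
  double max_step2 = 0.25 * fd.sigma_ref * fd.sigma_ref;
  // rare force pileups (many overlapping neighbours in a dense
  // cluster) have their deterministic displacement capped so the
  // actual move never exceeds half a bead diameter; the hard abort
  // fires when the raw deterministic displacement reaches two bead
  // diameters, the signature of a timestep that cannot resolve the
  // stiffest force (a diverging integration grows without bound, so
  // it always crosses this threshold)
  double cap_det = 0.25 * fd.sigma_ref;
  double abort_det2 = 4.0 * fd.sigma_ref * fd.sigma_ref;
  long n_clamped = 0;

  GetRNGstate();
  FastRng rng;
  rng.seed(unif_rand(), unif_rand(), unif_rand(), unif_rand());
  nl.build(s);
  int fail_particle = -1, fail_step = -1;
  double max_bond = 0.0, max_disp = 0.0;
  int fi = 0;

  for (int step = 1; step <= n_steps; ++step) {
    if (nl.needs_rebuild(s)) nl.build(s);
    std::fill(F.begin(), F.end(), 0.0);
    size_t np = nl.pi.size();
    for (size_t p = 0; p < np; ++p)
      pair_force(s, fd, nl.pi[p], nl.pj[p], F);
    bonded_forces(s, fd, &F, false);

    for (int i = 0; i < s.N; ++i) {
      if (pin_beads && i < s.n) continue;
      double gx = 0.0, gy = 0.0, gz = 0.0;
      if (noise) {
        gx = rng.norm(); gy = rng.norm(); gz = rng.norm();
      }
      double fx = s.D[i] * F[3 * i] * dt;
      double fy = s.D[i] * F[3 * i + 1] * dt;
      double fz = s.D[i] * F[3 * i + 2] * dt;
      double fmag2 = fx * fx + fy * fy + fz * fz;
      if (fmag2 > abort_det2) { fail_particle = i; fail_step = step; break; }
      if (fmag2 > cap_det * cap_det) {
        double sc = cap_det / std::sqrt(fmag2);
        fx *= sc; fy *= sc; fz *= sc;
        ++n_clamped;
      }
      double ddx = fx + sq2Ddt[i] * gx;
      double ddy = fy + sq2Ddt[i] * gy;
      double ddz = fz + sq2Ddt[i] * gz;
      double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (d2 > max_step2) {  // keep the total below the bound too
        double sc = std::sqrt(max_step2 / d2) * 0.999;
        ddx *= sc; ddy *= sc; ddz *= sc;
        d2 = max_step2 * 0.998;
      }
      if (d2 > max_disp) max_disp = d2;
      s.x[3 * i] += ddx; s.x[3 * i + 1] += ddy; s.x[3 * i + 2] += ddz;
    }
    if (fail_particle >= 0) break;

    if (any_switch) {
      for (int f = 0; f < s.m; ++f) {
        double p = s.comp[f] ? koff[f] * dt : kon[f] * dt;
        if (p > 0.0 && rng.unif() < p) s.comp[f] = !s.comp[f];
      }
    }

    if (step > equil && frame_every > 0 &&
        (step - equil) % frame_every == 0 && fi < nframes) {
      NumericMatrix fp(s.N, 3);
      for (int i = 0; i < s.N; ++i) {
        fp(i, 0) = s.x[3 * i]; fp(i, 1) = s.x[3 * i + 1];
        fp(i, 2) = s.x[3 * i + 2];
      }
      LogicalVector cf(s.m);
      for (int f = 0; f < s.m; ++f) cf[f] = s.comp[f] != 0;
      frames[fi] = fp; comps[fi] = cf; times[fi] = step * dt;
      ++fi;
      for (int i = 0; i + 1 < s.n; ++i) {
        double bx = s.x[3 * i] - s.x[3 * (i + 1)];
        double by = s.x[3 * i + 1] - s.x[3 * (i + 1) + 1];
        double bz = s.x[3 * i + 2] - s.x[3 * (i + 1) + 2];
        double bl = std::sqrt(bx * bx + by * by + bz * bz);
        if (bl > max_bond) max_bond = bl;
      }
    }
  }
  PutRNGstate();
  if (fail_particle >= 0)
    stop("BD step unstable at step %d: particle %d moved more than half "
         "a bead diameter; reduce the timestep", fail_step, fail_particle);

  NumericMatrix fpos(s.N, 3);
  for (int i = 0; i < s.N; ++i) {
    fpos(i, 0) = s.x[3 * i]; fpos(i, 1) = s.x[3 * i + 1];
    fpos(i, 2) = s.x[3 * i + 2];
  }
  LogicalVector fcomp(s.m);
  for (int f = 0; f < s.m; ++f) fcomp[f] = s.comp[f] != 0;
  return List::create(_["frames"] = frames, _["competent"] = comps,
                      _["times"] = times, _["final_positions"] = fpos,
                      _["final_competent"] = fcomp,
                      _["max_bond_length"] = max_bond,
                      _["max_step_displacement"] = std::sqrt(max_disp),
                      _["n_clamped"] = (double)n_clamped,
                      _["n_rebuilds"] = nl.n_rebuilds);
}

// one BD update (brute-force forces; intended for small test systems)
// [[Rcpp::export]]
NumericMatrix engine_step(NumericMatrix pos, int n_beads,
                          IntegerMatrix beadcol, IntegerVector fcol,
                          LogicalVector comp, NumericVector diam,
                          NumericVector D, NumericVector eps_spec,
                          NumericVector eps_ns, List field,
                          double dt, bool noise) {
  Sys s = build_sys(pos, n_beads, beadcol, fcol, comp, diam, D,
                    eps_spec, eps_ns);
  Field fd = read_field(field);
  std::vector<double> F(3 * s.N, 0.0);
  for (int i = 0; i < s.N; ++i)
    for (int j = i + 1; j < s.N; ++j) {
      if (i < s.n && j < s.n && j == i + 1) continue;
      pair_force(s, fd, i, j, F);
    }
  bonded_forces(s, fd, &F, false);
  NumericMatrix out(s.N, 3);
  GetRNGstate();
  for (int i = 0; i < s.N; ++i) {
    double gx = 0.0, gy = 0.0, gz = 0.0;
    if (noise && dt > 0) {
      gx = norm_rand(); gy = norm_rand(); gz = norm_rand();
    }
    double sq = std::sqrt(2.0 * s.D[i] * dt);
    out(i, 0) = s.x[3 * i] + s.D[i] * F[3 * i] * dt + sq * gx;
    out(i, 1) = s.x[3 * i + 1] + s.D[i] * F[3 * i + 1] * dt + sq * gy;
    out(i, 2) = s.x[3 * i + 2] + s.D[i] * F[3 * i + 2] * dt + sq * gz;
  }
  PutRNGstate();
  return out;
}
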