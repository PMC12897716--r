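// Compiled core: neighbour lists, pairwise forces, velocity-Verlet
// integration for the DPD and Langevin engines, and distance histograms.
//
// Everything runs in reduced units (kBT = 1, rc-scaled lengths, water-bead
// mass = 1). The engine stores wrapped positions plus per-bead image
// counters, so pair distances need only a single minimum-image fold while
// snapshots emit unwrapped coordinates (p + box * im) for polymer geometry.
// For cache efficiency the engine keeps beads sorted in cell order
// (the sort is re-applied at every neighbour-list rebuild) and maps back to
// the caller's bead numbering through a permutation. A private xorshift RNG
// keeps trajectories bit-reproducible for a given seed regardless of R's
// RNG state.

#pragma GCC optimize("O3", "unroll-loops")

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  inline uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  // uniform in [0, 1)
  inline double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // zero-mean unit-variance uniform on [-sqrt(3), sqrt(3)]
  inline double theta() { return 3.4641016151377544 * (unif() - 0.5); }
  bool have_spare = false;
  double spare = 0.0;
  inline double gauss() {
    if (have_spare) {
      have_spare = false;
      return spare;
    }
    double u1, u2;
    do {
      u1 = unif();
    } while (u1 <= 1e-300);
    u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(6.283185307179586 * u2);
    have_spare = true;
    return r * std::cos(6.283185307179586 * u2);
  }
};

inline double min_image(double d, double box) {
  return d - box * std::nearbyint(d / box);
}

inline double min_image_fast(double d, double box, double inv_box) {
  return d - box * std::floor(d * inv_box + 0.5);
}

// single fold for wrapped coordinates (|d| < box guaranteed)
inline double fold(double d, double box, double half_box) {
  if (d > half_box) return d - box;
  if (d < -half_box) return d + box;
  return d;
}

// Plain linked-cell half pair list on caller-ordered positions; used by the
// exported neighbour search (performance-uncritical path) and as the
// all-pairs fallback for boxes smaller than three cells.
void build_pairs_simple(const double* p, int n, double box, double rlist,
                        std::vector<int>& pi, std::vector<int>& pj) {
  pi.clear();
  pj.clear();
  const double r2max = rlist * rlist;
  const double inv_box = 1.0 / box;
  int nc = (int)std::floor(box / rlist);
  auto add_if = [&](int i, int j) {
    double dx = min_image_fast(p[3 * i] - p[3 * j], box, inv_box);
    double dy = min_image_fast(p[3 * i + 1] - p[3 * j + 1], box, inv_box);
    double dz = min_image_fast(p[3 * i + 2] - p[3 * j + 2], box, inv_box);
    if (dx * dx + dy * dy + dz * dz < r2max) {
      pi.push_back(i);
      pj.push_back(j);
    }
  };
  if (nc < 3) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) add_if(i, j);
    return;
  }
  double cell = box / nc;
  std::vector<int> head(nc * nc * nc, -1), nxt(n, -1);
  for (int i = 0; i < n; ++i) {
    double wx = p[3 * i] - box * std::floor(p[3 * i] * inv_box);
    double wy = p[3 * i + 1] - box * std::floor(p[3 * i + 1] * inv_box);
    double wz = p[3 * i + 2] - box * std::floor(p[3 * i + 2] * inv_box);
    int ix = (int)(wx / cell); if (ix >= nc) ix = nc - 1;
    int iy = (int)(wy / cell); if (iy >= nc) iy = nc - 1;
    int iz = (int)(wz / cell); if (iz >= nc) iz = nc - 1;
    int c = (ix * nc + iy) * nc + iz;
    nxt[i] = head[c];
    head[c] = i;
  }
  static const int off[13][3] = {
      {1, 0, 0},  {0, 1, 0},  {0, 0, 1},  {1, 1, 0},  {1, -1, 0},
      {1, 0, 1},  {1, 0, -1}, {0, 1, 1},  {0, 1, -1}, {1, 1, 1},
      {1, 1, -1}, {1, -1, 1}, {1, -1, -1}};
  for (int ix = 0; ix < nc; ++ix)
    for (int iy = 0; iy < nc; ++iy)
      for (int iz = 0; iz < nc; ++iz) {
        int c = (ix * nc + iy) * nc + iz;
        for (int i = head[c]; i >= 0; i = nxt[i]) {
          for (int j = nxt[i]; j >= 0; j = nxt[j]) add_if(i, j);
          for (int k = 0; k < 13; ++k) {
            int jx = (ix + off[k][0] + nc) % nc;
            int jy = (iy + off[k][1] + nc) % nc;
            int jz = (iz + off[k][2] + nc) % nc;
            int c2 = (jx * nc + jy) * nc + jz;
            for (int j = head[c2]; j >= 0; j = nxt[j]) add_if(i, j);
          }
        }
      }
}

enum Mode { MODE_DPD = 0, MODE_LANGEVIN_PRE = 1, MODE_LANGEVIN_IMPLICIT = 2 };

struct Engine {
  int n;
  double box, dt;
  int mode;
  // DPD parameters
  double amat[4];  // fmax by type pair, 2 types
  double gamma_dpd, sigma_dpd;
  // Langevin thermostat
  double gamma_lang;
  // implicit-solvent nonbonded (WCA + smoothed hydrophobic well)
  double wca_eps, wca_sig, hydro_depth, hydro_r1, hydro_r2, fcap;
  double cutoff;  // nonbonded interaction cutoff
  double skin = 0.3;

  // internal (cell-sorted) bead order; ext[i] = caller index of bead i
  // positions p are wrapped into [0, box); im counts box crossings so that
  // unwrapped coordinates are p + box * im
  std::vector<double> p, v, f, mass, p0;
  std::vector<int> im;
  std::vector<int> type, ext;
  std::vector<int> bonds_ext_i, bonds_ext_j;  // caller numbering (stable)
  std::vector<int> bi, bj;                    // internal numbering
  double bondK, bondR0;
  std::vector<int> pli, plj;  // half pair list, internal numbering
  // scratch for sorting
  std::vector<int> cell_of, count, order, inv, tmpi;
  std::vector<double> tmpd;
  int n_rebuilds = 0;

  void remap_bonds() {
    inv.resize(n);
    for (int i = 0; i < n; ++i) inv[ext[i]] = i;
    size_t nb = bonds_ext_i.size();
    bi.resize(nb);
    bj.resize(nb);
    for (size_t k = 0; k < nb; ++k) {
      bi[k] = inv[bonds_ext_i[k]];
      bj[k] = inv[bonds_ext_j[k]];
    }
  }

  void build_list() {
    ++n_rebuilds;
    const double rlist = cutoff + skin;
    const double inv_box = 1.0 / box;
    int nc = (int)std::floor(box / rlist);
    if (nc < 3) {
      build_pairs_simple(p.data(), n, box, rlist, pli, plj);
      p0 = p;
      return;
    }
    const double cell = box / nc;
    const int ncells = nc * nc * nc;

    // cell of each bead (positions are maintained wrapped in [0, box))
    cell_of.resize(n);
    const double inv_cell = nc * inv_box;
    for (int i = 0; i < n; ++i) {
      int ix = (int)(p[3 * i] * inv_cell); if (ix >= nc) ix = nc - 1;
      int iy = (int)(p[3 * i + 1] * inv_cell); if (iy >= nc) iy = nc - 1;
      int iz = (int)(p[3 * i + 2] * inv_cell); if (iz >= nc) iz = nc - 1;
      cell_of[i] = (ix * nc + iy) * nc + iz;
    }
    // stable counting sort into cell order
    count.assign(ncells + 1, 0);
    for (int i = 0; i < n; ++i) ++count[cell_of[i] + 1];
    for (int c = 0; c < ncells; ++c) count[c + 1] += count[c];
    order.resize(n);
    {
      tmpi.assign(count.begin(), count.end() - 1);
      for (int i = 0; i < n; ++i) order[tmpi[cell_of[i]]++] = i;
    }
    // permute p, v, mass, type, ext (forces are recomputed after rebuild)
    tmpd.resize(3 * n);
    for (int k = 0; k < n; ++k) {
      int s = order[k];
      tmpd[3 * k] = p[3 * s];
      tmpd[3 * k + 1] = p[3 * s + 1];
      tmpd[3 * k + 2] = p[3 * s + 2];
    }
    p.swap(tmpd);
    tmpd.resize(3 * n);
    for (int k = 0; k < n; ++k) {
      int s = order[k];
      tmpd[3 * k] = v[3 * s];
      tmpd[3 * k + 1] = v[3 * s + 1];
      tmpd[3 * k + 2] = v[3 * s + 2];
    }
    v.swap(tmpd);
    tmpd.resize(n);
    for (int k = 0; k < n; ++k) tmpd[k] = mass[order[k]];
    for (int k = 0; k < n; ++k) mass[k] = tmpd[k];
    tmpi.resize(n);
    for (int k = 0; k < n; ++k) tmpi[k] = type[order[k]];
    type.swap(tmpi);
    tmpi.resize(n);
    for (int k = 0; k < n; ++k) tmpi[k] = ext[order[k]];
    ext.swap(tmpi);
    tmpi.resize(3 * n);
    for (int k = 0; k < n; ++k) {
      int s = order[k];
      tmpi[3 * k] = im[3 * s];
      tmpi[3 * k + 1] = im[3 * s + 1];
      tmpi[3 * k + 2] = im[3 * s + 2];
    }
    im.swap(tmpi);
    remap_bonds();

    // pair list from contiguous cell ranges count[c] .. count[c+1]
    const double r2max = rlist * rlist;
    pli.clear();
    plj.clear();
    if (pli.capacity() == 0) {
      pli.reserve((size_t)(14.0 * n));
      plj.reserve((size_t)(14.0 * n));
    }
    const double* P = p.data();
    const double hb = 0.5 * box;
    auto add_range = [&](int i, int jlo, int jhi) {
      const double xi = P[3 * i], yi = P[3 * i + 1], zi = P[3 * i + 2];
      for (int j = jlo; j < jhi; ++j) {
        double dx = fold(xi - P[3 * j], box, hb);
        double dy = fold(yi - P[3 * j + 1], box, hb);
        double dz = fold(zi - P[3 * j + 2], box, hb);
        if (dx * dx + dy * dy + dz * dz < r2max) {
          pli.push_back(i);
          plj.push_back(j);
        }
      }
    };
    static const int off[13][3] = {
        {1, 0, 0},  {0, 1, 0},  {0, 0, 1},  {1, 1, 0},  {1, -1, 0},
        {1, 0, 1},  {1, 0, -1}, {0, 1, 1},  {0, 1, -1}, {1, 1, 1},
        {1, 1, -1}, {1, -1, 1}, {1, -1, -1}};
    for (int ix = 0; ix < nc; ++ix)
      for (int iy = 0; iy < nc; ++iy)
        for (int iz = 0; iz < nc; ++iz) {
          const int c = (ix * nc + iy) * nc + iz;
          const int lo = count[c], hi = count[c + 1];
          for (int i = lo; i < hi; ++i) add_range(i, i + 1, hi);
          for (int k = 0; k < 13; ++k) {
            int jx = (ix + off[k][0] + nc) % nc;
            int jy = (iy + off[k][1] + nc) % nc;
            int jz = (iz + off[k][2] + nc) % nc;
            const int c2 = (jx * nc + jy) * nc + jz;
            const int lo2 = count[c2], hi2 = count[c2 + 1];
            if (lo2 == hi2) continue;
            for (int i = lo; i < hi; ++i) add_range(i, lo2, hi2);
          }
        }
    p0 = p;
  }

  bool need_rebuild() const {
    const double lim = 0.25 * skin * skin;
    const double hb = 0.5 * box;
    for (int i = 0; i < 3 * n; i += 3) {
      double dx = fold(p[i] - p0[i], box, hb);
      double dy = fold(p[i + 1] - p0[i + 1], box, hb);
      double dz = fold(p[i + 2] - p0[i + 2], box, hb);
      if (dx * dx + dy * dy + dz * dz > lim) return true;
    }
    return false;
  }

  // fills f; random contributions drawn from rng when the thermostat is on
  void forces(Rng& rng, bool with_random) {
    std::fill(f.begin(), f.end(), 0.0);
    const double rc2 = cutoff * cutoff;
    const double inv_cutoff = 1.0 / cutoff;
    const double inv_sqrt_dt = 1.0 / std::sqrt(dt);
    const double hb = 0.5 * box;
    const size_t np = pli.size();
    const int* pi = pli.data();
    const int* pj = plj.data();
    const double* P = p.data();
    const double* V = v.data();
    double* F = f.data();
    for (size_t k = 0; k < np; ++k) {
      const int i3 = 3 * pi[k], j3 = 3 * pj[k];
      double dx = fold(P[i3] - P[j3], box, hb);
      double dy = fold(P[i3 + 1] - P[j3 + 1], box, hb);
      double dz = fold(P[i3 + 2] - P[j3 + 2], box, hb);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2) continue;
      double r = std::sqrt(r2);
      if (r < 1e-12) continue;  // exactly overlapping: no defined direction
      double inv_r = 1.0 / r;
      double fmag = 0.0;  // scalar force along r_hat (positive = repulsive)
      if (mode == MODE_LANGEVIN_IMPLICIT) {
        double wca_rc = 1.122462048309373 * wca_sig;
        if (r < wca_rc) {
          double sr2 = wca_sig * wca_sig / r2;
          double sr6 = sr2 * sr2 * sr2;
          fmag += 24.0 * wca_eps * (2.0 * sr6 * sr6 - sr6) * inv_r;
          if (fmag > fcap) fmag = fcap;
        }
        if (hydro_depth > 0.0 && r < hydro_r2 && r > hydro_r1) {
          // U = -depth * cos^2(pi/2 * (r-r1)/(r2-r1)); F = -dU/dr
          double w = hydro_r2 - hydro_r1;
          double u = (r - hydro_r1) / w;
          fmag += -hydro_depth * (M_PI / (2.0 * w)) * std::sin(M_PI * u);
        }
      } else {
        // DPD soft repulsion, F = a (1 - r/rc)
        double a = amat[type[pi[k]] * 2 + type[pj[k]]];
        fmag += a * (1.0 - r * inv_cutoff);
        if (mode == MODE_DPD) {
          double rvx = V[i3] - V[j3], rvy = V[i3 + 1] - V[j3 + 1],
                 rvz = V[i3 + 2] - V[j3 + 2];
          double vdotr = (rvx * dx + rvy * dy + rvz * dz) * inv_r;
          fmag -= gamma_dpd * vdotr;  // constant weight inside rc
          if (with_random) fmag += sigma_dpd * rng.theta() * inv_sqrt_dt;
        }
      }
      double c = fmag * inv_r;
      F[i3] += c * dx; F[i3 + 1] += c * dy; F[i3 + 2] += c * dz;
      F[j3] -= c * dx; F[j3 + 1] -= c * dy; F[j3 + 2] -= c * dz;
    }
    // harmonic bonds, F = -K (r - r0)
    const double hbb = 0.5 * box;
    for (size_t k = 0; k < bi.size(); ++k) {
      const int i3 = 3 * bi[k], j3 = 3 * bj[k];
      double dx = fold(p[i3] - p[j3], box, hbb);
      double dy = fold(p[i3 + 1] - p[j3 + 1], box, hbb);
      double dz = fold(p[i3 + 2] - p[j3 + 2], box, hbb);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) continue;
      double c = -bondK * (r - bondR0) / r;
      f[i3] += c * dx; f[i3 + 1] += c * dy; f[i3 + 2] += c * dz;
      f[j3] -= c * dx; f[j3 + 1] -= c * dy; f[j3 + 2] -= c * dz;
    }
    // per-bead Langevin thermostat (kBT = 1)
    if ((mode == MODE_LANGEVIN_PRE || mode == MODE_LANGEVIN_IMPLICIT) &&
        with_random) {
      const double amp = std::sqrt(2.0 * gamma_lang / dt);
      for (int i = 0; i < 3 * n; ++i) {
        f[i] += -gamma_lang * v[i] + amp * rng.gauss();
      }
    }
  }

  double kinetic_temperature() const {
    double px = 0, py = 0, pz = 0, M = 0;
    for (int i = 0; i < n; ++i) {
      px += mass[i] * v[3 * i];
      py += mass[i] * v[3 * i + 1];
      pz += mass[i] * v[3 * i + 2];
      M += mass[i];
    }
    px /= M; py /= M; pz /= M;
    double ke = 0;
    for (int i = 0; i < n; ++i) {
      double ax = v[3 * i] - px, ay = v[3 * i + 1] - py,
             az = v[3 * i + 2] - pz;
      ke += 0.5 * mass[i] * (ax * ax + ay * ay + az * az);
    }
    return 2.0 * ke / (3.0 * (n - 1));
  }
};

Engine make_engine(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
                   IntegerVector type, double box, double dt, List params,
                   IntegerMatrix bonds) {
  Engine e;
  e.n = pos.nrow();
  e.box = box;
  e.dt = dt;
  e.mode = as<int>(params["mode"]);
  NumericMatrix am = params["amat"];
  e.amat[0] = am(0, 0); e.amat[1] = am(0, 1);
  e.amat[2] = am(1, 0); e.amat[3] = am(1, 1);
  e.gamma_dpd = as<double>(params["gamma"]);
  e.sigma_dpd = as<double>(params["sigma"]);
  e.gamma_lang = as<double>(params["gamma_lang"]);
  e.wca_eps = as<double>(params["wca_eps"]);
  e.wca_sig = as<double>(params["wca_sigma"]);
  e.hydro_depth = as<double>(params["hydro_depth"]);
  e.hydro_r1 = as<double>(params["hydro_r1"]);
  e.hydro_r2 = as<double>(params["hydro_r2"]);
  e.fcap = as<double>(params["force_cap"]);
  e.cutoff = as<double>(params["cutoff"]);
  e.bondK = as<double>(params["bond_K"]);
  e.bondR0 = as<double>(params["bond_r0"]);
  e.p.resize(3 * e.n);
  e.im.resize(3 * e.n);
  e.v.resize(3 * e.n);
  e.f.resize(3 * e.n);
  e.mass.resize(e.n);
  e.type.resize(e.n);
  e.ext.resize(e.n);
  for (int i = 0; i < e.n; ++i) {
    for (int d = 0; d < 3; ++d) {
      double q = pos(i, d);
      int img = (int)std::floor(q / box);
      e.p[3 * i + d] = q - box * img;
      e.im[3 * i + d] = img;
    }
    e.v[3 * i] = vel(i, 0);
    e.v[3 * i + 1] = vel(i, 1);
    e.v[3 * i + 2] = vel(i, 2);
    e.mass[i] = mass[i];
    e.type[i] = type[i];
    e.ext[i] = i;
  }
  int nb = bonds.nrow();
  e.bonds_ext_i.resize(nb);
  e.bonds_ext_j.resize(nb);
  for (int k = 0; k < nb; ++k) {
    e.bonds_ext_i[k] = bonds(k, 0) - 1;
    e.bonds_ext_j[k] = bonds(k, 1) - 1;
  }
  e.remap_bonds();
  e.build_list();
  return e;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_all_pairs_within")]]
IntegerMatrix cpp_all_pairs_within(NumericMatrix pos, double cutoff) {
  int n = pos.nrow();
  std::vector<int> ai, aj;
  double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      if (dx * dx + dy * dy + dz * dz < c2) {
        ai.push_back(i + 1);
        aj.push_back(j + 1);
      }
    }
  IntegerMatrix out(ai.size(), 2);
  for (size_t k = 0; k < ai.size(); ++k) {
    out(k, 0) = ai[k];
    out(k, 1) = aj[k];
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_neighbor_pairs")]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix pos, double box,
                                 double cutoff) {
  int n = pos.nrow();
  std::vector<double> p(3 * n);
  for (int i = 0; i < n; ++i) {
    p[3 * i] = pos(i, 0);
    p[3 * i + 1] = pos(i, 1);
    p[3 * i + 2] = pos(i, 2);
  }
  std::vector<int> pi, pj;
  build_pairs_simple(p.data(), n, box, cutoff, pi, pj);
  IntegerMatrix out(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) {
    int a = pi[k] + 1, b = pj[k] + 1;
    out(k, 0) = std::min(a, b);
    out(k, 1) = std::max(a, b);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_compute_forces")]]
NumericMatrix cpp_compute_forces(NumericMatrix pos, NumericMatrix vel,
                                 NumericVector mass, IntegerVector type,
                                 double box, double dt, List params,
                                 IntegerMatrix bonds) {
  Engine e = make_engine(pos, vel, mass, type, box, dt, params, bonds);
  Rng rng(1);
  e.forces(rng, false);
  NumericMatrix out(e.n, 3);
  for (int i = 0; i < e.n; ++i) {
    out(e.ext[i], 0) = e.f[3 * i];
    out(e.ext[i], 1) = e.f[3 * i + 1];
    out(e.ext[i], 2) = e.f[3 * i + 2];
  }
  return out;
}

// Runs nsteps of velocity-Verlet with a single force evaluation per step.
// Returns updated state, snapshots (unwrapped positions, caller bead order)
// and a log of the kinetic temperature.
// [[Rcpp::export(name = ".cpp_run")]]
List cpp_run(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
             IntegerVector type, double box, double dt, int nsteps,
             List params, IntegerMatrix bonds, double seed,
             int snapshot_every, int log_every, int step_offset) {
  Engine e = make_engine(pos, vel, mass, type, box, dt, params, bonds);
  Rng rng((uint64_t)seed);
  const int n = e.n;
  const double half_dt = 0.5 * dt;
  const double lim = 0.5 * box;

  int nsnap = snapshot_every > 0 ? nsteps / snapshot_every : 0;
  NumericVector snaps(std::max(1, nsnap) * (R_xlen_t)n * 3);
  IntegerVector snap_steps(std::max(1, nsnap));
  int isnap = 0;
  int nlog = log_every > 0 ? nsteps / log_every : 0;
  NumericVector temps(std::max(1, nlog));
  IntegerVector temp_steps(std::max(1, nlog));
  int ilog = 0;

  e.forces(rng, true);
  for (int s = 1; s <= nsteps; ++s) {
    for (int i = 0; i < n; ++i) {
      const double im = half_dt / e.mass[i];
      e.v[3 * i] += im * e.f[3 * i];
      e.v[3 * i + 1] += im * e.f[3 * i + 1];
      e.v[3 * i + 2] += im * e.f[3 * i + 2];
      double ddx = dt * e.v[3 * i];
      double ddy = dt * e.v[3 * i + 1];
      double ddz = dt * e.v[3 * i + 2];
      if (std::fabs(ddx) > lim || std::fabs(ddy) > lim ||
          std::fabs(ddz) > lim) {
        stop("simulation blow-up at step %d (bead %d moved more than half "
             "the box in one step)",
             step_offset + s, e.ext[i] + 1);
      }
      for (int d = 0; d < 3; ++d) {
        double q = e.p[3 * i + d] + (d == 0 ? ddx : (d == 1 ? ddy : ddz));
        if (q >= box) {
          q -= box;
          ++e.im[3 * i + d];
        } else if (q < 0) {
          q += box;
          --e.im[3 * i + d];
        }
        e.p[3 * i + d] = q;
      }
    }
    if (e.need_rebuild()) e.build_list();
    e.forces(rng, true);
    for (int i = 0; i < n; ++i) {
      const double im = half_dt / e.mass[i];
      e.v[3 * i] += im * e.f[3 * i];
      e.v[3 * i + 1] += im * e.f[3 * i + 1];
      e.v[3 * i + 2] += im * e.f[3 * i + 2];
    }
    if (snapshot_every > 0 && s % snapshot_every == 0 && isnap < nsnap) {
      double* dst = REAL(snaps) + (R_xlen_t)isnap * n * 3;
      for (int i = 0; i < n; ++i) {
        const int o = e.ext[i];
        dst[o] = e.p[3 * i] + box * e.im[3 * i];
        dst[o + n] = e.p[3 * i + 1] + box * e.im[3 * i + 1];
        dst[o + 2 * n] = e.p[3 * i + 2] + box * e.im[3 * i + 2];
      }
      snap_steps[isnap] = step_offset + s;
      ++isnap;
    }
    if (log_every > 0 && s % log_every == 0 && ilog < nlog) {
      temps[ilog] = e.kinetic_temperature();
      temp_steps[ilog] = step_offset + s;
      ++ilog;
    }
    if (s % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix pos_out(n, 3), vel_out(n, 3);
  for (int i = 0; i < n; ++i) {
    const int o = e.ext[i];
    pos_out(o, 0) = e.p[3 * i] + box * e.im[3 * i];
    pos_out(o, 1) = e.p[3 * i + 1] + box * e.im[3 * i + 1];
    pos_out(o, 2) = e.p[3 * i + 2] + box * e.im[3 * i + 2];
    vel_out(o, 0) = e.v[3 * i];
    vel_out(o, 1) = e.v[3 * i + 1];
    vel_out(o, 2) = e.v[3 * i + 2];
  }
  return List::create(
      _["positions"] = pos_out, _["velocities"] = vel_out,
      _["snapshots"] = snaps, _["snapshot_steps"] = snap_steps,
      _["n_snapshots"] = isnap, _["temperatures"] = temps,
      _["temperature_steps"] = temp_steps, _["n_logs"] = ilog,
      _["n_rebuilds"] = e.n_rebuilds);
}

// Minimum-image distance from each row of `points` to the nearest row of
// `set`; used for rejection sampling during solvent fill.
// [[Rcpp::export(name = ".cpp_min_dist_to_set")]]
NumericVector cpp_min_dist_to_set(NumericMatrix points, NumericMatrix set,
                                  double box) {
  const int np = points.nrow(), ns = set.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < ns; ++j) {
      double dx = min_image(points(i, 0) - set(j, 0), box);
      double dy = min_image(points(i, 1) - set(j, 1), box);
      double dz = min_image(points(i, 2) - set(j, 2), box);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Histogram of minimum-image pair distances between rows of A and B.
// If same = true, A and B are the same group: each unordered distinct pair
// is counted once.
// [[Rcpp::export(name = ".cpp_pair_hist")]]
NumericVector cpp_pair_hist(NumericMatrix A, NumericMatrix B, double box,
                            double r_max, int nbins, bool same) {
  NumericVector h(nbins);
  const int na = A.nrow(), nb = B.nrow();
  const double w = r_max / nbins;
  const double r2max = r_max * r_max;
  for (int i = 0; i < na; ++i) {
    int j0 = same ? i + 1 : 0;
    for (int j = j0; j < nb; ++j) {
      double dx = min_image(A(i, 0) - B(j, 0), box);
      double dy = min_image(A(i, 1) - B(j, 1), box);
      double dz = min_image(A(i, 2) - B(j, 2), box);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= r2max) continue;
      int bin = (int)(std::sqrt(r2) / w);
      if (bin >= 0 && bin < nbins) h[bin] += 1.0;
    }
  }
  return h;
}
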