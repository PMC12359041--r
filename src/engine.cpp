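// Core Langevin dynamics engine for the bead-spring nucleus model.
//
// Units: length sigma = 1, energy kT = 1, mass m = 1. Bonds are
// finite-extensible (FENE, Kremer-Grest k = 30, R0 = 1.5 by default) plus a
// WCA core; non-bonded pairs interact via WCA (purely repulsive classes) or a
// truncated-shifted 12-6 potential with class-pair well depth (attractive
// classes). Integration is BAOAB Langevin (one force evaluation per step);
// with friction = 0 and temperature = 0 it reduces to velocity Verlet, which
// the energy-conservation tests exploit.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

struct CellGrid {
  double cell;            // cell edge length (>= list cutoff)
  double ox, oy, oz;      // origin
  int nx, ny, nz;
  std::vector<int> head;  // first particle index per cell, -1 terminated
  std::vector<int> next;

  void build(const std::vector<double>& x, int n, double cutoff) {
    cell = cutoff;
    double minx = 1e300, miny = 1e300, minz = 1e300;
    double maxx = -1e300, maxy = -1e300, maxz = -1e300;
    for (int i = 0; i < n; ++i) {
      minx = std::min(minx, x[3 * i]);     maxx = std::max(maxx, x[3 * i]);
      miny = std::min(miny, x[3 * i + 1]); maxy = std::max(maxy, x[3 * i + 1]);
      minz = std::min(minz, x[3 * i + 2]); maxz = std::max(maxz, x[3 * i + 2]);
    }
    ox = minx - 0.5 * cell; oy = miny - 0.5 * cell; oz = minz - 0.5 * cell;
    nx = std::max(1, (int)std::floor((maxx - ox) / cell) + 1);
    ny = std::max(1, (int)std::floor((maxy - oy) / cell) + 1);
    nz = std::max(1, (int)std::floor((maxz - oz) / cell) + 1);
    head.assign((size_t)nx * ny * nz, -1);
    next.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int cx = (int)((x[3 * i] - ox) / cell);
      int cy = (int)((x[3 * i + 1] - oy) / cell);
      int cz = (int)((x[3 * i + 2] - oz) / cell);
      cx = std::min(std::max(cx, 0), nx - 1);
      cy = std::min(std::max(cy, 0), ny - 1);
      cz = std::min(std::max(cz, 0), nz - 1);
      size_t c = (size_t)(cz * ny + cy) * nx + cx;
      next[i] = head[c];
      head[c] = i;
    }
  }
};

// Compressed adjacency for bonded-pair exclusion in the non-bonded loop.
struct BondAdj {
  std::vector<int> off;
  std::vector<int> nbr;
  void build(const IntegerMatrix& bonds, int n) {
    std::vector<int> deg(n, 0);
    int m = bonds.nrow();
    for (int b = 0; b < m; ++b) {
      ++deg[bonds(b, 0) - 1];
      ++deg[bonds(b, 1) - 1];
    }
    off.assign(n + 1, 0);
    for (int i = 0; i < n; ++i) off[i + 1] = off[i] + deg[i];
    nbr.assign(off[n], 0);
    std::vector<int> cur(off.begin(), off.end() - 1);
    for (int b = 0; b < m; ++b) {
      int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
      nbr[cur[i]++] = j;
      nbr[cur[j]++] = i;
    }
  }
  bool bonded(int i, int j) const {
    for (int k = off[i]; k < off[i + 1]; ++k)
      if (nbr[k] == j) return true;
    return false;
  }
};

struct Engine {
  int n;
  std::vector<double> x, v, f;
  std::vector<int> cls;            // 0-based class index into emat
  std::vector<double> emat;        // ncls x ncls well depths
  std::vector<double> smat2;       // ncls x ncls squared pair diameters
  int ncls;
  IntegerMatrix bonds;             // 1-based pairs
  BondAdj adj;

  double fene_k = 30.0;
  std::vector<double> r0b;    // per-bond maximum extension
  std::vector<int> styleb;    // 0 = FENE+WCA, 1 = harmonic(rest)+WCA
  std::vector<double> restb;  // per-bond rest length (harmonic only)
  double rc_attr = 2.5;
  double skin = 0.4;
  double r2min = 0.0;              // force-capping core (soft start); 0 = off

  // Verlet list
  std::vector<int> plist;          // flat i,j pairs (0-based)
  std::vector<double> x_ref;       // positions at last list build
  CellGrid grid;

  double rwca2 = std::pow(2.0, 1.0 / 3.0);  // (2^(1/6))^2

  void init(NumericMatrix pos, IntegerVector classes, IntegerMatrix bond_mat,
            NumericMatrix emat_in) {
    n = pos.nrow();
    x.resize(3 * n); v.assign(3 * n, 0.0); f.assign(3 * n, 0.0);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);
    cls.resize(n);
    for (int i = 0; i < n; ++i) cls[i] = classes[i] - 1;
    ncls = emat_in.nrow();
    emat.resize((size_t)ncls * ncls);
    smat2.assign((size_t)ncls * ncls, 1.0);
    for (int a = 0; a < ncls; ++a)
      for (int b = 0; b < ncls; ++b) emat[a * ncls + b] = emat_in(a, b);
    bonds = bond_mat;
    adj.build(bonds, n);
    r0b.assign(bonds.nrow(), 1.5);
    styleb.assign(bonds.nrow(), 0);
    restb.assign(bonds.nrow(), 0.0);
  }

  void set_bond_r0(NumericVector bond_r0) {
    if (bond_r0.size() == 1) {
      r0b.assign(bonds.nrow(), bond_r0[0]);
    } else {
      r0b.assign(bond_r0.begin(), bond_r0.end());
    }
  }

  void set_sigma(NumericMatrix smat_in) {
    for (int a = 0; a < ncls; ++a)
      for (int b = 0; b < ncls; ++b)
        smat2[a * ncls + b] = smat_in(a, b) * smat_in(a, b);
  }

  void set_bond_style(IntegerVector style, NumericVector rest) {
    if (style.size() == 1) styleb.assign(bonds.nrow(), style[0]);
    else styleb.assign(style.begin(), style.end());
    if (rest.size() == 1) restb.assign(bonds.nrow(), rest[0]);
    else restb.assign(rest.begin(), rest.end());
  }

  void build_list() {
    double rl = rc_attr + skin;
    grid.build(x, n, rl);
    double rl2 = rl * rl;
    plist.clear();
    for (int cz = 0; cz < grid.nz; ++cz)
      for (int cy = 0; cy < grid.ny; ++cy)
        for (int cx = 0; cx < grid.nx; ++cx) {
          size_t c = (size_t)(cz * grid.ny + cy) * grid.nx + cx;
          for (int i = grid.head[c]; i != -1; i = grid.next[i]) {
            // same cell: j after i in chain
            for (int j = grid.next[i]; j != -1; j = grid.next[j])
              try_pair(i, j, rl2);
            // half the neighbor cells (13 of 26)
            static const int off[13][3] = {
              {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
              {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
            for (int k = 0; k < 13; ++k) {
              int ax = cx + off[k][0], ay = cy + off[k][1], az = cz + off[k][2];
              if (ax < 0 || ay < 0 || az < 0 ||
                  ax >= grid.nx || ay >= grid.ny || az >= grid.nz) continue;
              size_t c2 = (size_t)(az * grid.ny + ay) * grid.nx + ax;
              for (int j = grid.head[c2]; j != -1; j = grid.next[j])
                try_pair(i, j, rl2);
            }
          }
        }
    x_ref = x;
  }

  inline void try_pair(int i, int j, double rl2) {
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < rl2 && !adj.bonded(i, j)) {
      plist.push_back(i);
      plist.push_back(j);
    }
  }

  bool list_stale() const {
    double lim = 0.25 * skin * skin;  // (skin/2)^2
    for (int i = 0; i < n; ++i) {
      double dx = x[3 * i] - x_ref[3 * i];
      double dy = x[3 * i + 1] - x_ref[3 * i + 1];
      double dz = x[3 * i + 2] - x_ref[3 * i + 2];
      if (dx * dx + dy * dy + dz * dz > lim) return true;
    }
    return false;
  }

  // Pair force kernel for one pair; accumulates forces, returns energy.
  inline double pair_kernel(int i, int j, bool want_energy) {
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    double eps = emat[cls[i] * ncls + cls[j]];
    double s2 = smat2[cls[i] * ncls + cls[j]];
    // attraction cutoff is absolute (the 2.5-sigma contact scale); only the
    // repulsive core scales with the pair diameter
    double rc2 = (eps > 0.0) ? rc_attr * rc_attr : rwca2 * s2;
    if (r2 >= rc2) return 0.0;
    double e = (eps > 0.0) ? eps : 1.0;
    double r2c = (r2min > 0.0 && r2 < r2min * s2) ? r2min * s2 : r2;
    double sr2 = s2 / r2c;
    double sr6 = sr2 * sr2 * sr2;
    double fmag = 24.0 * e * (2.0 * sr6 * sr6 - sr6) / r2c;  // F/r
    f[3 * i] += fmag * dx;  f[3 * j] -= fmag * dx;
    f[3 * i + 1] += fmag * dy;  f[3 * j + 1] -= fmag * dy;
    f[3 * i + 2] += fmag * dz;  f[3 * j + 2] -= fmag * dz;
    if (!want_energy) return 0.0;
    double u = 4.0 * e * (sr6 * sr6 - sr6);
    double src2 = s2 / rc2, src6 = src2 * src2 * src2;
    u -= 4.0 * e * (src6 * src6 - src6);  // shift to zero at cutoff
    return u;
  }

  // FENE + WCA (chain) or harmonic(rest) + WCA (shell/tether/crosslink).
  inline double bond_kernel(int b, bool want_energy, int step) {
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    double r02 = r0b[b] * r0b[b];
    if (r2 >= r02)
      stop("bond %d (subunits %d-%d) overstretched (r = %.3f >= %.2f) at step %d",
           b + 1, i + 1, j + 1, std::sqrt(r2), r0b[b], step);
    double fene, u = 0.0;
    if (styleb[b] == 0) {
      fene = -fene_k / (1.0 - r2 / r02);  // F/r (attractive)
      if (want_energy) u += -0.5 * fene_k * r02 * std::log(1.0 - r2 / r02);
    } else {
      double r = std::sqrt(std::max(r2, 1e-24));
      fene = -fene_k * (r - restb[b]) / r;
      if (want_energy) u += 0.5 * fene_k * (r - restb[b]) * (r - restb[b]);
    }
    if (r2 < rwca2) {
      double r2c = (r2min > 0.0 && r2 < r2min) ? r2min : r2;
      double sr2 = 1.0 / r2c;
      double sr6 = sr2 * sr2 * sr2;
      fene += 24.0 * (2.0 * sr6 * sr6 - sr6) * sr2;
      if (want_energy) u += 4.0 * (sr6 * sr6 - sr6) + 1.0;
    }
    f[3 * i] += fene * dx;  f[3 * j] -= fene * dx;
    f[3 * i + 1] += fene * dy;  f[3 * j + 1] -= fene * dy;
    f[3 * i + 2] += fene * dz;  f[3 * j + 2] -= fene * dz;
    return u;
  }

  double compute_forces(bool want_energy, int step) {
    std::fill(f.begin(), f.end(), 0.0);
    double u = 0.0;
    size_t np = plist.size() / 2;
    for (size_t p = 0; p < np; ++p)
      u += pair_kernel(plist[2 * p], plist[2 * p + 1], want_energy);
    int m = bonds.nrow();
    for (int b = 0; b < m; ++b) u += bond_kernel(b, want_energy, step);
    return u;
  }
};

}  // namespace

// Enumerate unordered pairs within `cutoff`, via cell binning. If idx_b is
// empty: pairs within idx_a; otherwise pairs (a in idx_a, b in idx_b) with
// disjoint role interpretation (returned as [a, b]). Indices are 1-based.
// [[Rcpp::export]]
IntegerMatrix cpp_pairs_within(NumericMatrix pos, double cutoff,
                               IntegerVector idx_a, IntegerVector idx_b) {
  int n = pos.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);
  std::vector<int> role(n, 0);  // 0 = excluded, 1 = a, 2 = b
  bool cross = idx_b.size() > 0;
  for (int k = 0; k < idx_a.size(); ++k) role[idx_a[k] - 1] = 1;
  for (int k = 0; k < idx_b.size(); ++k) role[idx_b[k] - 1] = 2;
  CellGrid grid;
  grid.build(x, n, std::max(cutoff, 1e-8));
  double c2 = cutoff * cutoff;
  std::vector<int> out;
  static const int off[13][3] = {
    {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
    {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
  auto consider = [&](int i, int j) {
    if (role[i] == 0 || role[j] == 0) return;
    int a = -1, b = -1;
    if (cross) {
      if (role[i] == 1 && role[j] == 2) { a = i; b = j; }
      else if (role[j] == 1 && role[i] == 2) { a = j; b = i; }
      else return;
    } else {
      a = std::min(i, j); b = std::max(i, j);
    }
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    if (dx * dx + dy * dy + dz * dz <= c2) {
      out.push_back(a + 1);
      out.push_back(b + 1);
    }
  };
  for (int cz = 0; cz < grid.nz; ++cz)
    for (int cy = 0; cy < grid.ny; ++cy)
      for (int cx = 0; cx < grid.nx; ++cx) {
        size_t c = (size_t)(cz * grid.ny + cy) * grid.nx + cx;
        for (int i = grid.head[c]; i != -1; i = grid.next[i]) {
          for (int j = grid.next[i]; j != -1; j = grid.next[j]) consider(i, j);
          for (int k = 0; k < 13; ++k) {
            int ax = cx + off[k][0], ay = cy + off[k][1], az = cz + off[k][2];
            if (ax < 0 || ay < 0 || az < 0 ||
                ax >= grid.nx || ay >= grid.ny || az >= grid.nz) continue;
            size_t c2i = (size_t)(az * grid.ny + ay) * grid.nx + ax;
            for (int j = grid.head[c2i]; j != -1; j = grid.next[j]) consider(i, j);
          }
        }
      }
  int m = out.size() / 2;
  IntegerMatrix res(m, 2);
  for (int p = 0; p < m; ++p) {
    res(p, 0) = out[2 * p];
    res(p, 1) = out[2 * p + 1];
  }
  return res;
}

// Non-bonded forces via the neighbor-list path (oracle-comparable).
// [[Rcpp::export]]
NumericMatrix cpp_pair_forces(NumericMatrix pos, IntegerVector classes,
                              IntegerMatrix bonds, NumericMatrix emat,
                              NumericMatrix smat, double rc_attr) {
  Engine e;
  e.init(pos, classes, bonds, emat);
  e.set_sigma(smat);
  e.rc_attr = rc_attr;
  e.build_list();
  std::fill(e.f.begin(), e.f.end(), 0.0);
  size_t np = e.plist.size() / 2;
  for (size_t p = 0; p < np; ++p)
    e.pair_kernel(e.plist[2 * p], e.plist[2 * p + 1], false);
  NumericMatrix out(e.n, 3);
  for (int i = 0; i < e.n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = e.f[3 * i + d];
  return out;
}

// Bonded (FENE + WCA core) forces only.
// [[Rcpp::export]]
NumericMatrix cpp_bond_forces(NumericMatrix pos, IntegerMatrix bonds,
                              double fene_k, NumericVector bond_r0,
                              IntegerVector bond_style,
                              NumericVector bond_rest) {
  int n = pos.nrow();
  IntegerVector classes(n, 1);
  NumericMatrix emat(1, 1);
  Engine e;
  e.init(pos, classes, bonds, emat);
  e.fene_k = fene_k;
  e.set_bond_r0(bond_r0);
  e.set_bond_style(bond_style, bond_rest);
  std::fill(e.f.begin(), e.f.end(), 0.0);
  for (int b = 0; b < bonds.nrow(); ++b) e.bond_kernel(b, false, 0);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = e.f[3 * i + d];
  return out;
}

// Total potential energy (pairs + bonds), neighbor-list path.
// [[Rcpp::export]]
double cpp_potential_energy(NumericMatrix pos, IntegerVector classes,
                            IntegerMatrix bonds, NumericMatrix emat,
                            NumericMatrix smat, double rc_attr, double fene_k,
                            NumericVector bond_r0, IntegerVector bond_style,
                            NumericVector bond_rest) {
  Engine e;
  e.init(pos, classes, bonds, emat);
  e.set_sigma(smat);
  e.rc_attr = rc_attr;
  e.fene_k = fene_k;
  e.set_bond_r0(bond_r0);
  e.set_bond_style(bond_style, bond_rest);
  e.build_list();
  return e.compute_forces(true, 0);
}

// Main integration loop.
//
// opts: n_steps, dt, friction, temperature, seed, record_every (frames; 0 =
//   only final), series_every, max_disp (displacement cap, 0 = off),
//   init_velocities (bool), init_kT, fene_k, fene_r0, rc_attr, skin,
//   energies (bool)
// protocol: list(type = "none" | "stretch" | "compress", ...)
//   stretch: idx_north, idx_south (1-based), stiffness, step_speed (sigma per
//     integration step), axis (1-3)
//   compress: stiffness, step_speed, axis, gap_pad (initial wall clearance)
// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, IntegerVector classes, IntegerMatrix bonds,
             NumericVector bond_r0, IntegerVector bond_style,
             NumericVector bond_rest, NumericMatrix emat, NumericMatrix smat,
             List opts, List protocol) {
  Engine e;
  e.init(pos, classes, bonds, emat);
  e.set_sigma(smat);
  e.set_bond_r0(bond_r0);
  e.set_bond_style(bond_style, bond_rest);
  int n_steps = as<int>(opts["n_steps"]);
  double dt = as<double>(opts["dt"]);
  double gamma = as<double>(opts["friction"]);
  double kT = as<double>(opts["temperature"]);
  uint64_t seed = (uint64_t)as<double>(opts["seed"]);
  int record_every = as<int>(opts["record_every"]);
  int series_every = as<int>(opts["series_every"]);
  double max_disp = as<double>(opts["max_disp"]);
  bool want_energy = as<bool>(opts["energies"]);
  e.fene_k = as<double>(opts["fene_k"]);
  e.rc_attr = as<double>(opts["rc_attr"]);
  e.skin = as<double>(opts["skin"]);
  if (max_disp > 0.0) e.r2min = 0.64;  // cap core forces during soft start

  std::mt19937_64 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  bool init_vel = as<bool>(opts["init_velocities"]);
  double init_kT = as<double>(opts["init_kT"]);
  if (init_vel) {
    double s = std::sqrt(init_kT);
    for (int i = 0; i < 3 * e.n; ++i) e.v[i] = s * gauss(rng);
  }

  // protocol setup
  std::string ptype = as<std::string>(protocol["type"]);
  int mode = ptype == "stretch" ? 1 : (ptype == "compress" ? 2 : 0);
  std::vector<int> idxN, idxS;
  double K = 0.0, step_speed = 0.0;
  int axis = 1;  // 0-based axis index; default y
  double anchorN = 0.0, anchorS = 0.0, wallT = 0.0, wallB = 0.0;
  if (mode == 1) {
    IntegerVector a = protocol["idx_north"], b = protocol["idx_south"];
    for (int k = 0; k < a.size(); ++k) idxN.push_back(a[k] - 1);
    for (int k = 0; k < b.size(); ++k) idxS.push_back(b[k] - 1);
    K = as<double>(protocol["stiffness"]);
    step_speed = as<double>(protocol["step_speed"]);
    axis = as<int>(protocol["axis"]) - 1;
    double cN = 0.0, cS = 0.0;
    for (int i : idxN) cN += e.x[3 * i + axis];
    for (int i : idxS) cS += e.x[3 * i + axis];
    anchorN = cN / idxN.size();
    anchorS = cS / idxS.size();
  } else if (mode == 2) {
    K = as<double>(protocol["stiffness"]);
    step_speed = as<double>(protocol["step_speed"]);
    axis = as<int>(protocol["axis"]) - 1;
    double pad = as<double>(protocol["gap_pad"]);
    double lo = 1e300, hi = -1e300;
    for (int i = 0; i < e.n; ++i) {
      lo = std::min(lo, e.x[3 * i + axis]);
      hi = std::max(hi, e.x[3 * i + axis]);
    }
    wallT = hi + pad;
    wallB = lo - pad;
  }

  // BAOAB coefficients
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(kT * (1.0 - c1 * c1));

  // soft-start velocity clamp: caps runaway speeds that the displacement
  // cap alone would let accumulate
  double vmax2 = (max_disp > 0.0) ? (max_disp / dt) * (max_disp / dt) : 0.0;
  auto clamp_velocities = [&](void) {
    if (max_disp <= 0.0) return;
    for (int i = 0; i < e.n; ++i) {
      double v2 = e.v[3 * i] * e.v[3 * i] + e.v[3 * i + 1] * e.v[3 * i + 1] +
                  e.v[3 * i + 2] * e.v[3 * i + 2];
      if (v2 > vmax2) {
        double sc = std::sqrt(vmax2 / v2);
        e.v[3 * i] *= sc; e.v[3 * i + 1] *= sc; e.v[3 * i + 2] *= sc;
      }
    }
  };

  std::vector<NumericMatrix> frames;
  std::vector<int> frame_steps;
  std::vector<double> s_step, s_anchorN, s_anchorS, s_comN, s_comS,
      s_forceN, s_forceS, s_gap, s_wallF, s_ke, s_pe;

  auto com = [&](const std::vector<int>& idx) {
    double c = 0.0;
    for (int i : idx) c += e.x[3 * i + axis];
    return c / idx.size();
  };

  auto apply_protocol = [&](void) -> std::pair<double, double> {
    // returns (forceN, forceS) or (wall force, gap)
    if (mode == 1) {
      double cN = com(idxN), cS = com(idxS);
      double fN = K * (anchorN - cN);  // along +axis when anchor ahead
      double fS = K * (anchorS - cS);
      double pN = fN / idxN.size(), pS = fS / idxS.size();
      for (int i : idxN) e.f[3 * i + axis] += pN;
      for (int i : idxS) e.f[3 * i + axis] += pS;
      return {fN, fS};
    }
    if (mode == 2) {
      double wf = 0.0;
      for (int i = 0; i < e.n; ++i) {
        double y = e.x[3 * i + axis];
        if (y > wallT) {
          e.f[3 * i + axis] += -K * (y - wallT);
          wf += K * (y - wallT);
        }
        if (y < wallB) {  // not exclusive: plates may overlap a particle
          e.f[3 * i + axis] += K * (wallB - y);
          wf += K * (wallB - y);
        }
      }
      return {wf, wallT - wallB};
    }
    return {0.0, 0.0};
  };

  // protocol observables are averaged over each series interval (the
  // instantaneous spring force fluctuates thermally; the interval mean is
  // the better estimator of the restraint force at that loading)
  double accA = 0.0, accB = 0.0, accComN = 0.0, accComS = 0.0;
  int accCount = 0;

  auto record_series = [&](int step, double a, double b, double ke, double pe) {
    s_step.push_back(step);
    if (mode == 1) {
      s_anchorN.push_back(anchorN);
      s_anchorS.push_back(anchorS);
      if (accCount > 0) {
        s_comN.push_back(accComN / accCount);
        s_comS.push_back(accComS / accCount);
        s_forceN.push_back(accA / accCount);
        s_forceS.push_back(accB / accCount);
      } else {
        s_comN.push_back(com(idxN));
        s_comS.push_back(com(idxS));
        s_forceN.push_back(a);
        s_forceS.push_back(b);
      }
    } else if (mode == 2) {
      s_wallF.push_back(accCount > 0 ? accA / accCount : a);
      s_gap.push_back(b);
    }
    if (want_energy) {
      s_ke.push_back(ke);
      s_pe.push_back(pe);
    }
    accA = accB = accComN = accComS = 0.0;
    accCount = 0;
  };

  auto snapshot = [&](int step) {
    NumericMatrix fr(e.n, 3);
    for (int i = 0; i < e.n; ++i)
      for (int d = 0; d < 3; ++d) fr(i, d) = e.x[3 * i + d];
    frames.push_back(fr);
    frame_steps.push_back(step);
  };

  e.build_list();
  double pe = e.compute_forces(want_energy, 0);
  {
    auto pf = apply_protocol();
    double ke = 0.0;
    if (want_energy)
      for (int i = 0; i < 3 * e.n; ++i) ke += 0.5 * e.v[i] * e.v[i];
    record_series(0, pf.first, pf.second, ke, pe);
  }
  snapshot(0);

  for (int step = 1; step <= n_steps; ++step) {
    // B: half kick
    for (int i = 0; i < 3 * e.n; ++i) e.v[i] += 0.5 * dt * e.f[i];
    clamp_velocities();
    // A: half drift (with optional displacement cap)
    for (int i = 0; i < e.n; ++i) {
      double dx = 0.5 * dt * e.v[3 * i];
      double dy = 0.5 * dt * e.v[3 * i + 1];
      double dz = 0.5 * dt * e.v[3 * i + 2];
      if (max_disp > 0.0) {
        double d2 = dx * dx + dy * dy + dz * dz;
        double lim = 0.5 * max_disp;
        if (d2 > lim * lim) {
          double sc = lim / std::sqrt(d2);
          dx *= sc; dy *= sc; dz *= sc;
        }
      }
      e.x[3 * i] += dx; e.x[3 * i + 1] += dy; e.x[3 * i + 2] += dz;
    }
    // O: thermostat
    if (gamma > 0.0 || kT > 0.0) {
      for (int i = 0; i < 3 * e.n; ++i)
        e.v[i] = c1 * e.v[i] + c2 * gauss(rng);
    }
    // A: half drift
    for (int i = 0; i < e.n; ++i) {
      double dx = 0.5 * dt * e.v[3 * i];
      double dy = 0.5 * dt * e.v[3 * i + 1];
      double dz = 0.5 * dt * e.v[3 * i + 2];
      if (max_disp > 0.0) {
        double d2 = dx * dx + dy * dy + dz * dz;
        double lim = 0.5 * max_disp;
        if (d2 > lim * lim) {
          double sc = lim / std::sqrt(d2);
          dx *= sc; dy *= sc; dz *= sc;
        }
      }
      e.x[3 * i] += dx; e.x[3 * i + 1] += dy; e.x[3 * i + 2] += dz;
    }
    // advance protocol geometry
    if (mode == 1) {
      anchorN += step_speed;
      anchorS -= step_speed;
    } else if (mode == 2) {
      wallT -= step_speed;
      wallB += step_speed;
    }
    // forces at new positions
    if (e.list_stale()) e.build_list();
    bool rec = (series_every > 0 && step % series_every == 0) || step == n_steps;
    pe = e.compute_forces(want_energy && rec, step);
    auto pf = apply_protocol();
    if (mode == 1) {
      accA += pf.first; accB += pf.second;
      accComN += com(idxN); accComS += com(idxS);
      ++accCount;
    } else if (mode == 2) {
      accA += pf.first;
      ++accCount;
    }
    // B: half kick
    for (int i = 0; i < 3 * e.n; ++i) e.v[i] += 0.5 * dt * e.f[i];
    clamp_velocities();

    if (rec) {
      double ke = 0.0;
      if (want_energy)
        for (int i = 0; i < 3 * e.n; ++i) ke += 0.5 * e.v[i] * e.v[i];
      record_series(step, pf.first, pf.second, ke, pe);
      if (!std::isfinite(e.x[0]) || !std::isfinite(e.f[0]))
        stop("non-finite coordinates at step %d", step);
    }
    if ((record_every > 0 && step % record_every == 0) || step == n_steps)
      snapshot(step);
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix xout(e.n, 3), vout(e.n, 3);
  for (int i = 0; i < e.n; ++i)
    for (int d = 0; d < 3; ++d) {
      xout(i, d) = e.x[3 * i + d];
      vout(i, d) = e.v[3 * i + d];
    }
  List series = List::create(
      _["step"] = s_step, _["anchor_north"] = s_anchorN,
      _["anchor_south"] = s_anchorS, _["com_north"] = s_comN,
      _["com_south"] = s_comS, _["force_north"] = s_forceN,
      _["force_south"] = s_forceS, _["wall_force"] = s_wallF,
      _["gap"] = s_gap, _["kinetic"] = s_ke, _["potential"] = s_pe);
  return List::create(
      _["positions"] = xout, _["velocities"] = vout,
      _["frames"] = wrap(frames), _["frame_steps"] = wrap(frame_steps),
      _["series"] = series);
}
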