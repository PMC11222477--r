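// Compiled core of the reduced reactive CG simulator: truncated-shifted
// Lennard-Jones + optional Yukawa screened Coulomb, harmonic bonds/angles,
// BAOAB Langevin integration, and the stochastic disulfide bonding scheme.
// Units: nm, ps, amu, kJ/mol. All randomness goes through R's RNG so a single
// set.seed() call makes runs bit-reproducible.
//
// The Verlet list is rebuilt through a linked-cell pass (falling back to a
// direct O(N^2) scan when the box is too small for 3 cells per dimension).

#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static inline double min_image(double d, double L) {
  return d - L * std::round(d / L);
}

// fast path for differences of wrapped coordinates, |d| < L
static inline double mi_w(double d, double hL, double L) {
  if (d > hL) return d - L;
  if (d < -hL) return d + L;
  return d;
}

struct Sys {
  long n_rebuilds = 0;
  int n;
  std::vector<double> x, y, z;       // wrapped positions
  std::vector<int> ix, iy, iz;       // image counts
  std::vector<double> vx, vy, vz;
  std::vector<double> fx, fy, fz;
  double Lx, Ly, Lz;
  std::vector<int> type;             // 0-based species index
  std::vector<double> mass, charge;
  int ntype;
  std::vector<double> epsM, sigM;    // ntype*ntype pair tables
  double cutoff;
  bool coulomb;
  double debye, bjerrum;
  // bonded terms
  std::vector<int> b_i, b_j; std::vector<double> b_r0, b_k;
  std::vector<int> a_i, a_j, a_k; std::vector<double> a_t0, a_kt;
  std::unordered_set<long long> excl;
  // reactive sites
  std::vector<int> s_bead, s_mono, s_core, s_partner; // partner: -1 free
  // neighbour list
  std::vector<int> nl_i, nl_j;
  std::vector<double> ref_ux, ref_uy, ref_uz;
  bool nl_valid = false;
  double pe = 0.0;

  long long key(int i, int j) const {
    int a = std::min(i, j), b = std::max(i, j);
    return (long long)a * (long long)n + b;
  }
  void add_excl(int i, int j) { excl.insert(key(i, j)); }
  void del_excl(int i, int j) { excl.erase(key(i, j)); }
  bool is_excl(int i, int j) const { return excl.count(key(i, j)) > 0; }

  double ux(int i) const { return x[i] + ix[i] * Lx; }
  double uy(int i) const { return y[i] + iy[i] * Ly; }
  double uz(int i) const { return z[i] + iz[i] * Lz; }

  void build_exclusions() {
    excl.clear();
    for (size_t b = 0; b < b_i.size(); ++b) add_excl(b_i[b], b_j[b]);
    for (size_t a = 0; a < a_i.size(); ++a) add_excl(a_i[a], a_k[a]);
  }

  void try_pair(int i, int j, double rl2, double hx, double hy, double hz) {
    double dx = mi_w(x[i] - x[j], hx, Lx);
    double dy = mi_w(y[i] - y[j], hy, Ly);
    double dz = mi_w(z[i] - z[j], hz, Lz);
    if (dx * dx + dy * dy + dz * dz < rl2 && !is_excl(i, j)) {
      nl_i.push_back(i); nl_j.push_back(j);
    }
  }

  void build_nlist(double skin) {
    double rl = cutoff + skin, rl2 = rl * rl;
    double hx = 0.5 * Lx, hy = 0.5 * Ly, hz = 0.5 * Lz;
    nl_i.clear(); nl_j.clear();
    int ncx = (int)(Lx / rl), ncy = (int)(Ly / rl), ncz = (int)(Lz / rl);
    if (ncx >= 3 && ncy >= 3 && ncz >= 3) {
      // linked-cell enumeration with a half stencil
      int ncells = ncx * ncy * ncz;
      std::vector<int> headv(ncells, -1), nxt(n, -1);
      auto cidx = [&](int cx, int cy, int cz) {
        return ((cx + ncx) % ncx) + ncx * (((cy + ncy) % ncy) + ncy * ((cz + ncz) % ncz));
      };
      for (int i = 0; i < n; ++i) {
        int cx = std::min((int)(x[i] / Lx * ncx), ncx - 1);
        int cy = std::min((int)(y[i] / Ly * ncy), ncy - 1);
        int cz = std::min((int)(z[i] / Lz * ncz), ncz - 1);
        int c = cidx(cx, cy, cz);
        nxt[i] = headv[c]; headv[c] = i;
      }
      // half stencil: self + 13 neighbour cells
      static const int st[13][3] = {
        {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
        {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
      for (int cz = 0; cz < ncz; ++cz) for (int cy = 0; cy < ncy; ++cy)
        for (int cx = 0; cx < ncx; ++cx) {
          int c = cidx(cx, cy, cz);
          for (int i = headv[c]; i >= 0; i = nxt[i]) {
            for (int j = nxt[i]; j >= 0; j = nxt[j])
              try_pair(std::min(i, j), std::max(i, j), rl2, hx, hy, hz);
            for (int s = 0; s < 13; ++s) {
              int c2 = cidx(cx + st[s][0], cy + st[s][1], cz + st[s][2]);
              for (int j = headv[c2]; j >= 0; j = nxt[j])
                try_pair(std::min(i, j), std::max(i, j), rl2, hx, hy, hz);
            }
          }
        }
    } else {
      for (int i = 0; i < n - 1; ++i)
        for (int j = i + 1; j < n; ++j)
          try_pair(i, j, rl2, hx, hy, hz);
    }
    n_rebuilds++;
    ref_ux.resize(n); ref_uy.resize(n); ref_uz.resize(n);
    for (int i = 0; i < n; ++i) { ref_ux[i] = ux(i); ref_uy[i] = uy(i); ref_uz[i] = uz(i); }
    nl_valid = true;
  }

  bool nlist_stale(double skin) const {
    if (!nl_valid) return true;
    double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < n; ++i) {
      double dx = ux(i) - ref_ux[i], dy = uy(i) - ref_uy[i], dz = uz(i) - ref_uz[i];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }

  void forces() {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    pe = 0.0;
    double rc2 = cutoff * cutoff;
    double hx = 0.5 * Lx, hy = 0.5 * Ly, hz = 0.5 * Lz;
    // nonbonded
    for (size_t p = 0; p < nl_i.size(); ++p) {
      int i = nl_i[p], j = nl_j[p];
      double dx = mi_w(x[i] - x[j], hx, Lx);
      double dy = mi_w(y[i] - y[j], hy, Ly);
      double dz = mi_w(z[i] - z[j], hz, Lz);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2) continue;
      int ti = type[i], tj = type[j];
      double eps = epsM[ti * ntype + tj], sig = sigM[ti * ntype + tj];
      double r = std::sqrt(r2);
      double fr = 0.0; // dV/dr
      if (eps > 0.0) {
        double hard = 0.4 * sig;
        if (r2 < hard * hard)
          stop("beads %d and %d closer than hard-core distance (%f nm)", i + 1, j + 1, hard);
        double sr2 = sig * sig / r2, sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
        double src2 = sig * sig / rc2, src6 = src2 * src2 * src2;
        pe += 4.0 * eps * (sr12 - sr6) - 4.0 * eps * (src6 * src6 - src6);
        fr += 4.0 * eps * (-12.0 * sr12 + 6.0 * sr6) / r;
      }
      if (coulomb && charge[i] != 0.0 && charge[j] != 0.0) {
        double pref = bjerrum * charge[i] * charge[j];
        double e = std::exp(-r / debye);
        double ec = std::exp(-cutoff / debye);
        pe += pref * (e / r - ec / cutoff);
        fr += -pref * e * (1.0 / r2 + 1.0 / (r * debye));
      }
      double s = -fr / r;
      fx[i] += s * dx; fy[i] += s * dy; fz[i] += s * dz;
      fx[j] -= s * dx; fy[j] -= s * dy; fz[j] -= s * dz;
    }
    // bonds
    for (size_t b = 0; b < b_i.size(); ++b) {
      int i = b_i[b], j = b_j[b];
      double dx = min_image(x[i] - x[j], Lx);
      double dy = min_image(y[i] - y[j], Ly);
      double dz = min_image(z[i] - z[j], Lz);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dr = r - b_r0[b];
      pe += 0.5 * b_k[b] * dr * dr;
      double s = -b_k[b] * dr / r;
      fx[i] += s * dx; fy[i] += s * dy; fz[i] += s * dz;
      fx[j] -= s * dx; fy[j] -= s * dy; fz[j] -= s * dz;
    }
    // angles (harmonic in theta)
    for (size_t a = 0; a < a_i.size(); ++a) {
      int i = a_i[a], j = a_j[a], k = a_k[a];
      double r1x = min_image(x[i] - x[j], Lx), r1y = min_image(y[i] - y[j], Ly), r1z = min_image(z[i] - z[j], Lz);
      double r2x = min_image(x[k] - x[j], Lx), r2y = min_image(y[k] - y[j], Ly), r2z = min_image(z[k] - z[j], Lz);
      double n1 = std::sqrt(r1x * r1x + r1y * r1y + r1z * r1z);
      double n2 = std::sqrt(r2x * r2x + r2y * r2y + r2z * r2z);
      double c = (r1x * r2x + r1y * r2y + r1z * r2z) / (n1 * n2);
      c = std::max(-1.0, std::min(1.0, c));
      double th = std::acos(c);
      double s = std::sqrt(1.0 - c * c);
      if (s < 1e-8) s = 1e-8;
      double dth = th - a_t0[a];
      pe += 0.5 * a_kt[a] * dth * dth;
      double coef = a_kt[a] * dth / s; // force prefactor: -dV/dcos
      double fix = coef * (r2x / (n1 * n2) - c * r1x / (n1 * n1));
      double fiy = coef * (r2y / (n1 * n2) - c * r1y / (n1 * n1));
      double fiz = coef * (r2z / (n1 * n2) - c * r1z / (n1 * n1));
      double fkx = coef * (r1x / (n1 * n2) - c * r2x / (n2 * n2));
      double fky = coef * (r1y / (n1 * n2) - c * r2y / (n2 * n2));
      double fkz = coef * (r1z / (n1 * n2) - c * r2z / (n2 * n2));
      fx[i] += fix; fy[i] += fiy; fz[i] += fiz;
      fx[k] += fkx; fy[k] += fky; fz[k] += fkz;
      fx[j] -= fix + fkx; fy[j] -= fiy + fky; fz[j] -= fiz + fkz;
    }
  }
};

static Sys make_sys(NumericMatrix pos, IntegerMatrix img, NumericMatrix vel,
                    NumericVector box, IntegerVector type1, NumericVector mass,
                    NumericVector charge, NumericMatrix epsM, NumericMatrix sigM,
                    double cutoff, bool coulomb, double debye, double bjerrum,
                    NumericMatrix bonds, NumericMatrix angles) {
  Sys S;
  S.n = pos.nrow();
  S.Lx = box[0]; S.Ly = box[1]; S.Lz = box[2];
  S.x.resize(S.n); S.y.resize(S.n); S.z.resize(S.n);
  S.ix.resize(S.n); S.iy.resize(S.n); S.iz.resize(S.n);
  S.vx.resize(S.n); S.vy.resize(S.n); S.vz.resize(S.n);
  S.fx.resize(S.n); S.fy.resize(S.n); S.fz.resize(S.n);
  S.type.resize(S.n); S.mass.resize(S.n); S.charge.resize(S.n);
  for (int i = 0; i < S.n; ++i) {
    S.x[i] = pos(i, 0); S.y[i] = pos(i, 1); S.z[i] = pos(i, 2);
    S.ix[i] = img(i, 0); S.iy[i] = img(i, 1); S.iz[i] = img(i, 2);
    S.vx[i] = vel(i, 0); S.vy[i] = vel(i, 1); S.vz[i] = vel(i, 2);
    S.type[i] = type1[i] - 1;
    S.mass[i] = mass[i]; S.charge[i] = charge[i];
  }
  S.ntype = epsM.nrow();
  S.epsM.assign(epsM.begin(), epsM.end());
  S.sigM.assign(sigM.begin(), sigM.end());
  S.cutoff = cutoff; S.coulomb = coulomb; S.debye = debye; S.bjerrum = bjerrum;
  for (int b = 0; b < bonds.nrow(); ++b) {
    S.b_i.push_back((int)bonds(b, 0) - 1);
    S.b_j.push_back((int)bonds(b, 1) - 1);
    S.b_r0.push_back(bonds(b, 2));
    S.b_k.push_back(bonds(b, 3));
  }
  for (int a = 0; a < angles.nrow(); ++a) {
    S.a_i.push_back((int)angles(a, 0) - 1);
    S.a_j.push_back((int)angles(a, 1) - 1);
    S.a_k.push_back((int)angles(a, 2) - 1);
    S.a_t0.push_back(angles(a, 3));
    S.a_kt.push_back(angles(a, 4));
  }
  S.build_exclusions();
  return S;
}

// [[Rcpp::export(name = ".forces_cpp")]]
List forces_cpp(NumericMatrix pos, IntegerMatrix img, NumericMatrix vel,
                NumericVector box, IntegerVector type, NumericVector mass,
                NumericVector charge, NumericMatrix epsM, NumericMatrix sigM,
                double cutoff, bool coulomb, double debye, double bjerrum,
                NumericMatrix bonds, NumericMatrix angles) {
  Sys S = make_sys(pos, img, vel, box, type, mass, charge, epsM, sigM,
                   cutoff, coulomb, debye, bjerrum, bonds, angles);
  if (S.n > 0) { S.build_nlist(0.0); S.forces(); }
  NumericMatrix F(S.n, 3);
  for (int i = 0; i < S.n; ++i) { F(i, 0) = S.fx[i]; F(i, 1) = S.fy[i]; F(i, 2) = S.fz[i]; }
  return List::create(_["forces"] = F, _["energy"] = S.pe);
}

// [[Rcpp::export(name = ".neighbor_pairs_cpp")]]
IntegerMatrix neighbor_pairs_cpp(NumericMatrix pos, NumericVector box, double cutoff) {
  int n = pos.nrow();
  double rc2 = cutoff * cutoff;
  std::vector<int> pi, pj;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = min_image(pos(i, 0) - pos(j, 0), box[0]);
      double dy = min_image(pos(i, 1) - pos(j, 1), box[1]);
      double dz = min_image(pos(i, 2) - pos(j, 2), box[2]);
      if (dx * dx + dy * dy + dz * dz <= rc2) { pi.push_back(i + 1); pj.push_back(j + 1); }
    }
  }
  IntegerMatrix out(pi.size(), 2);
  for (size_t p = 0; p < pi.size(); ++p) { out(p, 0) = pi[p]; out(p, 1) = pj[p]; }
  return out;
}

struct Cand { double d; int i, j; };

// one reaction sweep over the site table; returns number of events appended
static void react_sweep(Sys &S, double dt_attempt, double r_react, double k_on,
                        double well_E, double k0_off, double kT,
                        double rb_r0, double rb_k, double ra_t0, double ra_kt,
                        double t_now,
                        std::vector<double> &ev_t, std::vector<int> &ev_i,
                        std::vector<int> &ev_j, std::vector<int> &ev_kind) {
  int ns = S.s_bead.size();
  double p_form = 1.0 - std::exp(-k_on * dt_attempt);
  std::vector<Cand> cands;
  double rr2 = r_react * r_react;
  for (int a = 0; a < ns - 1; ++a) {
    if (S.s_partner[a] >= 0) continue;
    for (int b = a + 1; b < ns; ++b) {
      if (S.s_partner[b] >= 0) continue;
      if (S.s_mono[a] == S.s_mono[b]) continue;
      int i = S.s_bead[a], j = S.s_bead[b];
      double dx = min_image(S.x[i] - S.x[j], S.Lx);
      double dy = min_image(S.y[i] - S.y[j], S.Ly);
      double dz = min_image(S.z[i] - S.z[j], S.Lz);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 <= rr2) cands.push_back({std::sqrt(d2), a, b});
    }
  }
  std::sort(cands.begin(), cands.end(), [](const Cand &u, const Cand &v) {
    if (u.d != v.d) return u.d < v.d;
    if (u.i != v.i) return u.i < v.i;
    return u.j < v.j;
  });
  std::vector<char> used(ns, 0);
  bool changed = false;
  for (auto &c : cands) {
    if (used[c.i] || used[c.j]) continue;
    if (S.s_partner[c.i] >= 0 || S.s_partner[c.j] >= 0) continue;
    if (unif_rand() < p_form) {
      S.s_partner[c.i] = c.j; S.s_partner[c.j] = c.i;
      used[c.i] = used[c.j] = 1;
      int ti = S.s_bead[c.i], tj = S.s_bead[c.j];
      int ci = S.s_core[c.i], cj = S.s_core[c.j];
      S.b_i.push_back(ti); S.b_j.push_back(tj); S.b_r0.push_back(rb_r0); S.b_k.push_back(rb_k);
      S.a_i.push_back(ci); S.a_j.push_back(ti); S.a_k.push_back(tj); S.a_t0.push_back(ra_t0); S.a_kt.push_back(ra_kt);
      S.a_i.push_back(ti); S.a_j.push_back(tj); S.a_k.push_back(cj); S.a_t0.push_back(ra_t0); S.a_kt.push_back(ra_kt);
      S.add_excl(ti, tj); S.add_excl(ci, tj); S.add_excl(ti, cj);
      ev_t.push_back(t_now); ev_i.push_back(c.i + 1); ev_j.push_back(c.j + 1); ev_kind.push_back(1);
      changed = true;
    }
  }
  if (k0_off > 0.0 && kT > 0.0) {
    double rate = k0_off * std::exp(-well_E / kT);
    double p_break = 1.0 - std::exp(-rate * dt_attempt);
    for (int a = 0; a < ns; ++a) {
      int b = S.s_partner[a];
      if (b <= a) continue;           // count each bonded pair once
      if (used[a] || used[b]) continue;
      if (unif_rand() < p_break) {
        int ti = S.s_bead[a], tj = S.s_bead[b];
        int ci = S.s_core[a], cj = S.s_core[b];
        for (size_t q = 0; q < S.b_i.size(); ++q) {
          if ((S.b_i[q] == ti && S.b_j[q] == tj) || (S.b_i[q] == tj && S.b_j[q] == ti)) {
            S.b_i.erase(S.b_i.begin() + q); S.b_j.erase(S.b_j.begin() + q);
            S.b_r0.erase(S.b_r0.begin() + q); S.b_k.erase(S.b_k.begin() + q);
            break;
          }
        }
        for (size_t q = S.a_i.size(); q-- > 0; ) {
          bool has_i = (S.a_i[q] == ti || S.a_j[q] == ti || S.a_k[q] == ti);
          bool has_j = (S.a_i[q] == tj || S.a_j[q] == tj || S.a_k[q] == tj);
          if (has_i && has_j) {
            S.a_i.erase(S.a_i.begin() + q); S.a_j.erase(S.a_j.begin() + q);
            S.a_k.erase(S.a_k.begin() + q); S.a_t0.erase(S.a_t0.begin() + q);
            S.a_kt.erase(S.a_kt.begin() + q);
          }
        }
        S.del_excl(ti, tj); S.del_excl(ci, tj); S.del_excl(ti, cj);
        S.s_partner[a] = -1; S.s_partner[b] = -1;
        used[a] = used[b] = 1;
        ev_t.push_back(t_now); ev_i.push_back(a + 1); ev_j.push_back(b + 1); ev_kind.push_back(2);
        changed = true;
      }
    }
  }
  if (changed) S.nl_valid = false;
}

// [[Rcpp::export(name = ".run_core_cpp")]]
List run_core_cpp(NumericMatrix pos, IntegerMatrix img, NumericMatrix vel,
                  NumericVector box, IntegerVector type, NumericVector mass,
                  NumericVector charge, NumericMatrix epsM, NumericMatrix sigM,
                  double cutoff, bool coulomb, double debye, double bjerrum,
                  NumericMatrix bonds, NumericMatrix angles,
                  IntegerVector site_bead, IntegerVector site_mono,
                  IntegerVector site_core, IntegerVector site_partner,
                  double r_react, double k_on, double well_E, double k0_off,
                  int attempt_interval, double rb_r0, double rb_k,
                  double ra_t0, double ra_kt, bool react_on,
                  double dt, double gamma, double kT, int n_steps,
                  int out_interval, double skin, double t0,
                  int bias_bead, double bias_k, double bias_center, int bias_axis,
                  IntegerVector ref_group) {
  Sys S = make_sys(pos, img, vel, box, type, mass, charge, epsM, sigM,
                   cutoff, coulomb, debye, bjerrum, bonds, angles);
  int ns = site_bead.size();
  S.s_bead.resize(ns); S.s_mono.resize(ns); S.s_core.resize(ns); S.s_partner.resize(ns);
  for (int s = 0; s < ns; ++s) {
    S.s_bead[s] = site_bead[s] - 1;
    S.s_mono[s] = site_mono[s];
    S.s_core[s] = site_core[s] - 1;
    S.s_partner[s] = site_partner[s] - 1; // 0 (free) -> -1
  }
  double c1 = std::exp(-gamma * dt);
  double half = 0.5 * dt;
  double Lmin = std::min(S.Lx, std::min(S.Ly, S.Lz));
  double dmax = 0.5 * Lmin;

  std::vector<double> ev_t; std::vector<int> ev_i, ev_j, ev_kind;
  List fr_times, fr_pos, fr_img, fr_vel, fr_pe;
  std::vector<double> times, pes;
  std::vector<NumericMatrix> Fpos, Fvel;
  std::vector<IntegerMatrix> Fimg;

  auto snapshot = [&](double t) {
    NumericMatrix P(S.n, 3), V(S.n, 3);
    IntegerMatrix I(S.n, 3);
    for (int i = 0; i < S.n; ++i) {
      if (!std::isfinite(S.x[i]) || !std::isfinite(S.y[i]) || !std::isfinite(S.z[i]))
        stop("non-finite position at t=%f ps (last valid frame: %d)", t, (int)times.size());
      P(i, 0) = S.x[i]; P(i, 1) = S.y[i]; P(i, 2) = S.z[i];
      V(i, 0) = S.vx[i]; V(i, 1) = S.vy[i]; V(i, 2) = S.vz[i];
      I(i, 0) = S.ix[i]; I(i, 1) = S.iy[i]; I(i, 2) = S.iz[i];
    }
    times.push_back(t); pes.push_back(S.pe);
    Fpos.push_back(P); Fvel.push_back(V); Fimg.push_back(I);
  };

  if (S.n > 0) { S.build_nlist(skin); S.forces(); }

  auto apply_bias = [&]() {
    if (bias_bead <= 0) return;
    int tb = bias_bead - 1;
    double L = (bias_axis == 0) ? S.Lx : (bias_axis == 1 ? S.Ly : S.Lz);
    double zt = (bias_axis == 0) ? S.x[tb] : (bias_axis == 1 ? S.y[tb] : S.z[tb]);
    double zref, fshare = 0.0;
    int ng = ref_group.size();
    if (ng > 0) {
      // circular-mean reference along the biased axis (periodic-safe)
      double sw = 0.0, cs = 0.0, sn = 0.0;
      for (int g = 0; g < ng; ++g) {
        int i = ref_group[g] - 1;
        double zi = (bias_axis == 0) ? S.x[i] : (bias_axis == 1 ? S.y[i] : S.z[i]);
        double th = 2.0 * M_PI * zi / L;
        cs += S.mass[i] * std::cos(th); sn += S.mass[i] * std::sin(th);
        sw += S.mass[i];
      }
      zref = std::atan2(sn / sw, cs / sw) * L / (2.0 * M_PI);
      fshare = 1.0 / sw;
    } else {
      zref = 0.5 * L;
    }
    double xi = min_image(zt - zref, L);
    double f = -bias_k * (xi - bias_center);
    S.pe += 0.5 * bias_k * (xi - bias_center) * (xi - bias_center);
    if (bias_axis == 0) S.fx[tb] += f; else if (bias_axis == 1) S.fy[tb] += f; else S.fz[tb] += f;
    if (ng > 0) {
      for (int g = 0; g < ng; ++g) {
        int i = ref_group[g] - 1;
        double fi = -f * S.mass[i] * fshare; // mass-weighted reaction force
        if (bias_axis == 0) S.fx[i] += fi; else if (bias_axis == 1) S.fy[i] += fi; else S.fz[i] += fi;
      }
    }
  };
  apply_bias();
  snapshot(t0);

  auto drift = [&](double hdt) {
    for (int i = 0; i < S.n; ++i) {
      double dx = hdt * S.vx[i], dy = hdt * S.vy[i], dz = hdt * S.vz[i];
      if (std::fabs(dx) > dmax || std::fabs(dy) > dmax || std::fabs(dz) > dmax)
        stop("bead %d moved more than half the box in one step: reduce the timestep", i + 1);
      S.x[i] += dx; S.y[i] += dy; S.z[i] += dz;
      if (S.x[i] >= S.Lx) { S.x[i] -= S.Lx; S.ix[i] += 1; } else if (S.x[i] < 0) { S.x[i] += S.Lx; S.ix[i] -= 1; }
      if (S.y[i] >= S.Ly) { S.y[i] -= S.Ly; S.iy[i] += 1; } else if (S.y[i] < 0) { S.y[i] += S.Ly; S.iy[i] -= 1; }
      if (S.z[i] >= S.Lz) { S.z[i] -= S.Lz; S.iz[i] += 1; } else if (S.z[i] < 0) { S.z[i] += S.Lz; S.iz[i] -= 1; }
    }
  };

  for (int step = 1; step <= n_steps; ++step) {
    if (step % 512 == 0) Rcpp::checkUserInterrupt();
    // B
    for (int i = 0; i < S.n; ++i) {
      double im = half / S.mass[i];
      S.vx[i] += im * S.fx[i]; S.vy[i] += im * S.fy[i]; S.vz[i] += im * S.fz[i];
    }
    // A
    drift(half);
    // O
    if (gamma > 0.0) {
      for (int i = 0; i < S.n; ++i) {
        double c2 = std::sqrt(kT * (1.0 - c1 * c1) / S.mass[i]);
        S.vx[i] = c1 * S.vx[i] + c2 * norm_rand();
        S.vy[i] = c1 * S.vy[i] + c2 * norm_rand();
        S.vz[i] = c1 * S.vz[i] + c2 * norm_rand();
      }
    }
    // A
    drift(half);
    // forces at new positions
    if (S.n > 0) {
      if (S.nlist_stale(skin)) S.build_nlist(skin);
      S.forces();
      apply_bias();
    }
    // B
    for (int i = 0; i < S.n; ++i) {
      double im = half / S.mass[i];
      S.vx[i] += im * S.fx[i]; S.vy[i] += im * S.fy[i]; S.vz[i] += im * S.fz[i];
    }
    double t_now = t0 + step * dt;
    if (react_on && ns > 0 && attempt_interval > 0 && step % attempt_interval == 0) {
      size_t nev = ev_t.size();
      react_sweep(S, attempt_interval * dt, r_react, k_on, well_E, k0_off, kT,
                  rb_r0, rb_k, ra_t0, ra_kt, t_now, ev_t, ev_i, ev_j, ev_kind);
      if (ev_t.size() != nev && S.n > 0) { // topology changed: refresh forces
        S.build_nlist(skin);
        S.forces();
        apply_bias();
      }
    }
    if (step % out_interval == 0 || step == n_steps) snapshot(t_now);
  }

  int nf = times.size();
  List LP(nf), LV(nf), LI(nf);
  for (int f = 0; f < nf; ++f) { LP[f] = Fpos[f]; LV[f] = Fvel[f]; LI[f] = Fimg[f]; }
  NumericMatrix bonds_out(S.b_i.size(), 4);
  for (size_t b = 0; b < S.b_i.size(); ++b) {
    bonds_out(b, 0) = S.b_i[b] + 1; bonds_out(b, 1) = S.b_j[b] + 1;
    bonds_out(b, 2) = S.b_r0[b]; bonds_out(b, 3) = S.b_k[b];
  }
  NumericMatrix angles_out(S.a_i.size(), 5);
  for (size_t a = 0; a < S.a_i.size(); ++a) {
    angles_out(a, 0) = S.a_i[a] + 1; angles_out(a, 1) = S.a_j[a] + 1; angles_out(a, 2) = S.a_k[a] + 1;
    angles_out(a, 3) = S.a_t0[a]; angles_out(a, 4) = S.a_kt[a];
  }
  IntegerVector partner_out(ns);
  for (int s = 0; s < ns; ++s) partner_out[s] = S.s_partner[s] + 1;
  return List::create(
    _["times"] = wrap(times), _["pe"] = wrap(pes),
    _["positions"] = LP, _["velocities"] = LV, _["images"] = LI,
    _["event_time"] = wrap(ev_t), _["event_i"] = wrap(ev_i),
    _["event_j"] = wrap(ev_j), _["event_kind"] = wrap(ev_kind),
    _["bonds"] = bonds_out, _["angles"] = angles_out,
    _["site_partner"] = partner_out,
    _["n_rebuilds"] = (double)S.n_rebuilds);
}
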