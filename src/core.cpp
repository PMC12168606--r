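// Core numerics: pairwise energies under the minimum-image convention,
// semi-rigid-molecule Metropolis Monte Carlo, pair-distance histograms and
// periodic single-linkage clustering. All energies kJ/mol, distances A.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>
#include <random>
#include <functional>
#include <cstdint>
using namespace Rcpp;

static const double KB = 0.008314462618;     // kJ/mol/K
static const double KE = 1389.35457644382;   // kJ A / mol / e^2 (Coulomb)
static const double HARD_CORE = 0.5;         // A; below this a move is rejected outright
static const double E_HUGE = 1.0e12;

// --- deterministic RNG (mt19937_64 with explicit scaling so results do not
// --- depend on libstdc++ distribution internals)
struct Rng {
  std::mt19937_64 eng;
  explicit Rng(uint64_t seed) : eng(seed) {}
  double unif() { return (eng() >> 11) * (1.0 / 9007199254740992.0); }
  double sym(double h) { return (2.0 * unif() - 1.0) * h; }
  int pick(int n) { return (int)(unif() * n) % n; }
};

// branchy minimum image: coordinates are kept within ~one box length of the
// primary cell (molecules are re-wrapped after accepted moves), so the loops
// run 0-1 iterations and avoid a libm rounding call in the hot path
static inline double mimg(double d, double L) {
  double h = 0.5 * L;
  while (d > h) d -= L;
  while (d < -h) d += L;
  return d;
}

// Pair-type index for empirical potentials over heavy types {0=C,1=OG,2=OW}
static const int EP_IDX[3][3] = {{0, 1, 2}, {1, 3, 4}, {2, 4, 5}};

struct System {
  std::vector<double> x, y, z;     // atom coordinates (unwrapped)
  double L;                        // box edge
  std::vector<int> ljt;            // per-atom LJ type
  std::vector<double> q;           // per-atom charge
  std::vector<int> heavy;          // per-atom heavy type (-1 for H)
  std::vector<int> mol_of;         // per-atom molecule id
  std::vector<int> mstart, mlen;   // per-molecule atom ranges
  int nmol, natom, ntype;
  // precomputed LJ tables per type pair
  std::vector<double> c12, c6, ljshift;
  double rc, rc2;
  // empirical potential table: nr x 6, spacing ep_dr (zero row count => off)
  std::vector<double> ep;
  int ep_nr;
  double ep_dr;
  // per-molecule centre and bounding radius
  std::vector<double> cx, cy, cz, rad;

  // shift a molecule by whole box lengths so its centre lies in [0, L)
  void wrap_mol(int m) {
    double sx = std::floor(cx[m] / L) * L;
    double sy = std::floor(cy[m] / L) * L;
    double sz = std::floor(cz[m] / L) * L;
    if (sx == 0.0 && sy == 0.0 && sz == 0.0) return;
    int s = mstart[m], n = mlen[m];
    for (int i = s; i < s + n; ++i) { x[i] -= sx; y[i] -= sy; z[i] -= sz; }
    cx[m] -= sx; cy[m] -= sy; cz[m] -= sz;
  }

  void update_mol_geom(int m) {
    int s = mstart[m], n = mlen[m];
    double sx = 0, sy = 0, sz = 0;
    for (int i = s; i < s + n; ++i) { sx += x[i]; sy += y[i]; sz += z[i]; }
    cx[m] = sx / n; cy[m] = sy / n; cz[m] = sz / n;
    double r2m = 0;
    for (int i = s; i < s + n; ++i) {
      double dx = x[i] - cx[m], dy = y[i] - cy[m], dz = z[i] - cz[m];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > r2m) r2m = r2;
    }
    rad[m] = std::sqrt(r2m);
  }

  inline double pair_energy(int i, int j) const {
    double dx = mimg(x[i] - x[j], L), dy = mimg(y[i] - y[j], L), dz = mimg(z[i] - z[j], L);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2) return 0.0;
    if (r2 < HARD_CORE * HARD_CORE) return E_HUGE;
    double r = std::sqrt(r2);
    double e = 0.0;
    int tp = ljt[i] * ntype + ljt[j];
    if (c12[tp] != 0.0 || c6[tp] != 0.0) {
      double ir2 = 1.0 / r2, ir6 = ir2 * ir2 * ir2;
      e += c12[tp] * ir6 * ir6 - c6[tp] * ir6 - ljshift[tp];
    }
    double qq = q[i] * q[j];
    if (qq != 0.0) e += KE * qq * (1.0 / r - 1.0 / rc + (r - rc) / (rc * rc));
    if (ep_nr > 0 && heavy[i] >= 0 && heavy[j] >= 0) {
      double u = r / ep_dr;
      int k = (int)u;
      if (k < ep_nr - 1) {
        double f = u - k;
        int p = EP_IDX[heavy[i]][heavy[j]];
        const double *col = &ep[(size_t)p * ep_nr];
        e += col[k] * (1.0 - f) + col[k + 1] * f;
      }
    }
    return e;
  }

  // energy of molecule m with all other molecules, optionally using trial
  // coordinates tx,ty,tz for m's atoms
  double mol_energy(int m, const double *tx, const double *ty, const double *tz) {
    int s = mstart[m], n = mlen[m];
    double tcx = 0, tcy = 0, tcz = 0, trad = rad[m];
    if (tx) {
      for (int i = 0; i < n; ++i) { tcx += tx[i]; tcy += ty[i]; tcz += tz[i]; }
      tcx /= n; tcy /= n; tcz /= n;
      double r2m = 0;
      for (int i = 0; i < n; ++i) {
        double dx = tx[i] - tcx, dy = ty[i] - tcy, dz = tz[i] - tcz;
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 > r2m) r2m = r2;
      }
      trad = std::sqrt(r2m);
    } else { tcx = cx[m]; tcy = cy[m]; tcz = cz[m]; }
    double e = 0.0;
    for (int o = 0; o < nmol; ++o) {
      if (o == m) continue;
      double rx = tcx - cx[o], ry = tcy - cy[o], rz = tcz - cz[o];
      double dx = mimg(rx, L), dy = mimg(ry, L), dz = mimg(rz, L);
      double cut = rc + trad + rad[o];
      if (dx * dx + dy * dy + dz * dz > cut * cut) continue;
      int so = mstart[o], no = mlen[o];
      // when every atom pair of this molecule pair shares the centre
      // displacement's periodic image, hoist the image shift out of the
      // inner loop
      bool fast = (cut + trad + rad[o]) < 0.5 * L;
      double sxx = rx - dx, syy = ry - dy, szz = rz - dz;
      for (int a = 0; a < n; ++a) {
        double ax = tx ? tx[a] : x[s + a];
        double ay = ty ? ty[a] : y[s + a];
        double az = tz ? tz[a] : z[s + a];
        double axs = ax - sxx, ays = ay - syy, azs = az - szz;
        for (int b = so; b < so + no; ++b) {
          double ddx, ddy, ddz;
          if (fast) {
            ddx = axs - x[b]; ddy = ays - y[b]; ddz = azs - z[b];
          } else {
            ddx = mimg(ax - x[b], L); ddy = mimg(ay - y[b], L); ddz = mimg(az - z[b], L);
          }
          double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
          if (r2 >= rc2) continue;
          if (r2 < HARD_CORE * HARD_CORE) return E_HUGE;
          double r = std::sqrt(r2);
          double ee = 0.0;
          int ia = s + a;
          int tp = ljt[ia] * ntype + ljt[b];
          if (c12[tp] != 0.0 || c6[tp] != 0.0) {
            double ir2 = 1.0 / r2, ir6 = ir2 * ir2 * ir2;
            ee += c12[tp] * ir6 * ir6 - c6[tp] * ir6 - ljshift[tp];
          }
          double qq = q[ia] * q[b];
          if (qq != 0.0) ee += KE * qq * (1.0 / r - 1.0 / rc + (r - rc) / (rc * rc));
          if (ep_nr > 0 && heavy[ia] >= 0 && heavy[b] >= 0) {
            double u = r / ep_dr;
            int k = (int)u;
            if (k < ep_nr - 1) {
              double f = u - k;
              int p = EP_IDX[heavy[ia]][heavy[b]];
              const double *col = &ep[(size_t)p * ep_nr];
              ee += col[k] * (1.0 - f) + col[k + 1] * f;
            }
          }
          e += ee;
          if (e >= E_HUGE) return E_HUGE;
        }
      }
    }
    return e;
  }
};

static System build_system(NumericMatrix coords, double L, IntegerVector ljtype,
                           NumericVector charge, NumericVector eps, NumericVector sig,
                           IntegerVector heavy, IntegerVector mol_start,
                           IntegerVector mol_len, NumericMatrix ep_table,
                           double ep_dr, double rc) {
  System S;
  int N = coords.nrow();
  S.natom = N; S.L = L;
  S.x.resize(N); S.y.resize(N); S.z.resize(N);
  for (int i = 0; i < N; ++i) { S.x[i] = coords(i, 0); S.y[i] = coords(i, 1); S.z[i] = coords(i, 2); }
  S.ljt = as<std::vector<int>>(ljtype);
  S.q = as<std::vector<double>>(charge);
  S.heavy = as<std::vector<int>>(heavy);
  S.nmol = mol_start.size();
  S.mstart = as<std::vector<int>>(mol_start);
  S.mlen = as<std::vector<int>>(mol_len);
  S.mol_of.assign(N, 0);
  for (int m = 0; m < S.nmol; ++m)
    for (int i = S.mstart[m]; i < S.mstart[m] + S.mlen[m]; ++i) S.mol_of[i] = m;
  S.ntype = eps.size();
  S.rc = rc; S.rc2 = rc * rc;
  S.c12.assign(S.ntype * S.ntype, 0.0);
  S.c6.assign(S.ntype * S.ntype, 0.0);
  S.ljshift.assign(S.ntype * S.ntype, 0.0);
  for (int a = 0; a < S.ntype; ++a)
    for (int b = 0; b < S.ntype; ++b) {
      double e = std::sqrt(eps[a] * eps[b]);
      double s = 0.5 * (sig[a] + sig[b]);
      if (e > 0) {
        double s6 = std::pow(s, 6.0);
        double A = 4.0 * e * s6 * s6, B = 4.0 * e * s6;
        double irc6 = 1.0 / std::pow(rc, 6.0);
        S.c12[a * S.ntype + b] = A;
        S.c6[a * S.ntype + b] = B;
        S.ljshift[a * S.ntype + b] = A * irc6 * irc6 - B * irc6;
      }
    }
  S.ep_nr = ep_table.nrow();
  S.ep_dr = ep_dr;
  if (S.ep_nr > 0) {
    S.ep.resize((size_t)S.ep_nr * 6);
    for (int p = 0; p < 6; ++p)
      for (int k = 0; k < S.ep_nr; ++k) S.ep[(size_t)p * S.ep_nr + k] = ep_table(k, p);
  }
  S.cx.resize(S.nmol); S.cy.resize(S.nmol); S.cz.resize(S.nmol); S.rad.resize(S.nmol);
  for (int m = 0; m < S.nmol; ++m) { S.update_mol_geom(m); S.wrap_mol(m); }
  return S;
}

// [[Rcpp::export]]
double cpp_total_inter_energy(NumericMatrix coords, double L, IntegerVector ljtype,
                              NumericVector charge, NumericVector eps, NumericVector sig,
                              IntegerVector heavy, IntegerVector mol_start,
                              IntegerVector mol_len, NumericMatrix ep_table,
                              double ep_dr, double rc) {
  System S = build_system(coords, L, ljtype, charge, eps, sig, heavy,
                          mol_start, mol_len, ep_table, ep_dr, rc);
  double e = 0.0;
  for (int i = 0; i < S.natom; ++i)
    for (int j = i + 1; j < S.natom; ++j) {
      if (S.mol_of[i] == S.mol_of[j]) continue;
      double ee = S.pair_energy(i, j);
      if (ee >= E_HUGE) return E_HUGE;
      e += ee;
    }
  return e;
}

static void rodrigues(double &px, double &py, double &pz,
                      double ux, double uy, double uz, double c, double s) {
  double dot = ux * px + uy * py + uz * pz;
  double rx = px * c + (uy * pz - uz * py) * s + ux * dot * (1 - c);
  double ry = py * c + (uz * px - ux * pz) * s + uy * dot * (1 - c);
  double rz = pz * c + (ux * py - uy * px) * s + uz * dot * (1 - c);
  px = rx; py = ry; pz = rz;
}

static void rand_axis(Rng &rng, double &ux, double &uy, double &uz) {
  double a, b, s;
  do { a = 2 * rng.unif() - 1; b = 2 * rng.unif() - 1; s = a * a + b * b; } while (s >= 1 || s == 0);
  double h = 2 * std::sqrt(1 - s);
  ux = a * h; uy = b * h; uz = 1 - 2 * s;
}

// rot_groups: integer matrix, one row per (molecule, group, moved atom):
// columns mol, group, axis_a, axis_b, moved (0-based atom indices)
// [[Rcpp::export]]
List cpp_mc_run(NumericMatrix coords, double L, IntegerVector ljtype,
                NumericVector charge, NumericVector eps, NumericVector sig,
                IntegerVector heavy, IntegerVector mol_start, IntegerVector mol_len,
                IntegerMatrix rot_groups, NumericMatrix ep_table, double ep_dr,
                double rc, double temperature, int n_sweeps,
                NumericVector move_max,      // (translation A, rotation rad, dihedral rad)
                NumericVector move_weights,  // probabilities, sum 1
                double seed_u, int snapshot_every, bool tune) {
  System S = build_system(coords, L, ljtype, charge, eps, sig, heavy,
                          mol_start, mol_len, ep_table, ep_dr, rc);
  Rng rng((uint64_t)seed_u);
  double kT = KB * temperature;

  // per-molecule rotatable groups: (n_moved, [moved..., axis_a, axis_b])
  std::vector<std::vector<std::pair<int, std::vector<int>>>> groups(S.nmol);
  {
    std::map<std::pair<int, int>, std::vector<int>> tmp; // (mol,group) -> moved atoms
    std::map<std::pair<int, int>, std::pair<int, int>> ax;
    for (int r = 0; r < rot_groups.nrow(); ++r) {
      std::pair<int, int> key(rot_groups(r, 0), rot_groups(r, 1));
      tmp[key].push_back(rot_groups(r, 4));
      ax[key] = std::make_pair(rot_groups(r, 2), rot_groups(r, 3));
    }
    for (auto &kv : tmp) {
      int m = kv.first.first;
      std::vector<int> atoms = kv.second;
      atoms.push_back(ax[kv.first].first);   // encode axis in front
      atoms.push_back(ax[kv.first].second);
      groups[m].push_back(std::make_pair((int)atoms.size() - 2, atoms));
    }
  }

  double h_tr = move_max[0], h_rot = move_max[1], h_dih = move_max[2];
  double w_tr = move_weights[0], w_rot = move_weights[1];
  long att[3] = {0, 0, 0}, acc[3] = {0, 0, 0};
  long att_win[3] = {0, 0, 0}, acc_win[3] = {0, 0, 0};

  double e_total = 0.0;
  {
    for (int i = 0; i < S.natom; ++i)
      for (int j = i + 1; j < S.natom; ++j) {
        if (S.mol_of[i] == S.mol_of[j]) continue;
        e_total += S.pair_energy(i, j);
      }
  }
  double e_initial = e_total;
  double de_accum = 0.0;

  std::vector<double> tx, ty, tz;
  NumericVector etrace(n_sweeps);
  List snapshots;

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int mv = 0; mv < S.nmol; ++mv) {
      int m = rng.pick(S.nmol);
      int s = S.mstart[m], n = S.mlen[m];
      double u = rng.unif();
      int mtype;
      if (u < w_tr) mtype = 0;
      else if (u < w_tr + w_rot) mtype = (n > 1) ? 1 : 0;
      else mtype = groups[m].empty() ? 0 : 2;
      att[mtype]++; att_win[mtype]++;

      tx.assign(S.x.begin() + s, S.x.begin() + s + n);
      ty.assign(S.y.begin() + s, S.y.begin() + s + n);
      tz.assign(S.z.begin() + s, S.z.begin() + s + n);
      bool moved = true;
      if (mtype == 0) {
        double dx = rng.sym(h_tr), dy = rng.sym(h_tr), dz = rng.sym(h_tr);
        if (h_tr == 0.0) moved = false;
        for (int i = 0; i < n; ++i) { tx[i] += dx; ty[i] += dy; tz[i] += dz; }
      } else if (mtype == 1) {
        double ux, uy, uz; rand_axis(rng, ux, uy, uz);
        double ang = rng.sym(h_rot);
        if (h_rot == 0.0) moved = false;
        double c = std::cos(ang), sn = std::sin(ang);
        for (int i = 0; i < n; ++i) {
          double px = tx[i] - S.cx[m], py = ty[i] - S.cy[m], pz = tz[i] - S.cz[m];
          rodrigues(px, py, pz, ux, uy, uz, c, sn);
          tx[i] = px + S.cx[m]; ty[i] = py + S.cy[m]; tz[i] = pz + S.cz[m];
        }
      } else {
        int gi = rng.pick((int)groups[m].size());
        const std::vector<int> &ga = groups[m][gi].second;
        int nmove = groups[m][gi].first;
        int aA = ga[nmove], aB = ga[nmove + 1];
        double ax = S.x[aA], ay = S.y[aA], az = S.z[aA];
        double ux = S.x[aB] - ax, uy = S.y[aB] - ay, uz = S.z[aB] - az;
        double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
        ux /= nrm; uy /= nrm; uz /= nrm;
        double ang = rng.sym(h_dih);
        if (h_dih == 0.0) moved = false;
        double c = std::cos(ang), sn = std::sin(ang);
        for (int k = 0; k < nmove; ++k) {
          int i = ga[k] - s;
          double px = tx[i] - ax, py = ty[i] - ay, pz = tz[i] - az;
          rodrigues(px, py, pz, ux, uy, uz, c, sn);
          tx[i] = px + ax; ty[i] = py + ay; tz[i] = pz + az;
        }
      }

      if (!moved) { acc[mtype]++; acc_win[mtype]++; continue; }
      double e_old = S.mol_energy(m, nullptr, nullptr, nullptr);
      double e_new = S.mol_energy(m, tx.data(), ty.data(), tz.data());
      double dE = e_new - e_old;
      bool ok = false;
      if (e_new < E_HUGE) {
        if (dE <= 0) ok = true;
        else if (rng.unif() < std::exp(-dE / kT)) ok = true;
      } else if (e_old >= E_HUGE) {
        // both states sit in the hard-core region (only reachable from a
        // pathological start): let the molecule diffuse out
        ok = true;
        dE = 0.0;
      }
      if (ok) {
        for (int i = 0; i < n; ++i) { S.x[s + i] = tx[i]; S.y[s + i] = ty[i]; S.z[s + i] = tz[i]; }
        S.update_mol_geom(m);
        S.wrap_mol(m);
        e_total += dE;
        de_accum += dE;
        acc[mtype]++; acc_win[mtype]++;
      }
    }
    etrace[sweep] = e_total;

    if (tune && (sweep + 1) % 10 == 0) {
      double *hs[3] = {&h_tr, &h_rot, &h_dih};
      double hi[3] = {0.45 * L, 3.14159265358979, 3.14159265358979};
      for (int t = 0; t < 3; ++t) {
        if (att_win[t] > 20) {
          double a = (double)acc_win[t] / att_win[t];
          if (a < 0.30) *hs[t] *= 0.85;
          else if (a > 0.50) *hs[t] *= 1.15;
          if (*hs[t] > hi[t]) *hs[t] = hi[t];
          if (*hs[t] < 1e-4) *hs[t] = 1e-4;
        }
        att_win[t] = acc_win[t] = 0;
      }
    }
    if (snapshot_every > 0 && (sweep + 1) % snapshot_every == 0) {
      NumericMatrix snap(S.natom, 3);
      for (int i = 0; i < S.natom; ++i) { snap(i, 0) = S.x[i]; snap(i, 1) = S.y[i]; snap(i, 2) = S.z[i]; }
      snapshots.push_back(snap);
    }
    if ((sweep & 31) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(S.natom, 3);
  for (int i = 0; i < S.natom; ++i) { out(i, 0) = S.x[i]; out(i, 1) = S.y[i]; out(i, 2) = S.z[i]; }
  NumericVector accf(3), attv(3);
  for (int t = 0; t < 3; ++t) { accf[t] = att[t] ? (double)acc[t] / att[t] : 1.0; attv[t] = (double)att[t]; }
  return List::create(_["coords"] = out, _["snapshots"] = snapshots,
                      _["acceptance"] = accf, _["attempts"] = attv,
                      _["energy_trace"] = etrace,
                      _["move_max"] = NumericVector::create(h_tr, h_rot, h_dih),
                      _["energy_initial"] = e_initial,
                      _["energy_final"] = e_total,
                      _["delta_e_accumulated"] = de_accum);
}

// all-pair distance histograms by atom group; group < 0 excludes the atom.
// Returns nbins x npair counts of unordered pairs; pair index for a<=b is
// a*ng - a*(a-1)/2 + (b-a).
// [[Rcpp::export]]
NumericMatrix cpp_pair_histogram(List snapshots, double L, IntegerVector group,
                                 int ngroups, double dr, double rmax,
                                 IntegerVector mol_id, bool include_intra) {
  int nbins = (int)std::ceil(rmax / dr);
  int npair = ngroups * (ngroups + 1) / 2;
  NumericMatrix hist(nbins, npair);
  double rmax2 = rmax * rmax;
  for (int si = 0; si < snapshots.size(); ++si) {
    NumericMatrix C = snapshots[si];
    int N = C.nrow();
    for (int i = 0; i < N; ++i) {
      int gi = group[i];
      if (gi < 0) continue;
      for (int j = i + 1; j < N; ++j) {
        int gj = group[j];
        if (gj < 0) continue;
        if (!include_intra && mol_id[i] == mol_id[j]) continue;
        double dx = mimg(C(i, 0) - C(j, 0), L);
        double dy = mimg(C(i, 1) - C(j, 1), L);
        double dz = mimg(C(i, 2) - C(j, 2), L);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= rmax2) continue;
        int bin = (int)(std::sqrt(r2) / dr);
        if (bin >= nbins) continue;
        int a = gi < gj ? gi : gj, b = gi < gj ? gj : gi;
        int p = a * ngroups - a * (a - 1) / 2 + (b - a);
        hist(bin, p) += 1.0;
      }
    }
    if ((si & 7) == 0) Rcpp::checkUserInterrupt();
  }
  return hist;
}

// count unordered intermolecular pairs within cutoff between index sets A and
// B; same_set = true means A and B are the same selection (count i<j once),
// otherwise the sets must be disjoint
// [[Rcpp::export]]
double cpp_pair_count(NumericMatrix coords, double L, IntegerVector selA,
                      IntegerVector selB, double cutoff, IntegerVector mol_id,
                      bool same_set) {
  double c2 = cutoff * cutoff;
  long count = 0;
  for (int ia = 0; ia < selA.size(); ++ia) {
    int i = selA[ia];
    int jb0 = same_set ? ia + 1 : 0;
    for (int jb = jb0; jb < selB.size(); ++jb) {
      int j = selB[jb];
      if (mol_id[i] == mol_id[j]) continue;
      double dx = mimg(coords(i, 0) - coords(j, 0), L);
      double dy = mimg(coords(i, 1) - coords(j, 1), L);
      double dz = mimg(coords(i, 2) - coords(j, 2), L);
      if (dx * dx + dy * dy + dz * dz <= c2) ++count;
    }
  }
  return (double)count;
}

// sizes of connected components of points under periodic cutoff linkage
// [[Rcpp::export]]
IntegerVector cpp_cluster_sizes(NumericMatrix pts, double L, double cutoff) {
  int n = pts.nrow();
  std::vector<int> parent(n), rank_(n, 0);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = mimg(pts(i, 0) - pts(j, 0), L);
      double dy = mimg(pts(i, 1) - pts(j, 1), L);
      double dz = mimg(pts(i, 2) - pts(j, 2), L);
      if (dx * dx + dy * dy + dz * dz <= c2) {
        int a = find(i), b = find(j);
        if (a != b) {
          if (rank_[a] < rank_[b]) std::swap(a, b);
          parent[b] = a;
          if (rank_[a] == rank_[b]) rank_[a]++;
        }
      }
    }
  std::map<int, int> sizes;
  for (int i = 0; i < n; ++i) sizes[find(i)]++;
  IntegerVector out(sizes.size());
  int k = 0;
  for (auto &kv : sizes) out[k++] = kv.second;
  return out;
}

// minimum intermolecular atom-atom distance (A)
// [[Rcpp::export]]
double cpp_min_inter_dist(NumericMatrix coords, double L, IntegerVector mol_id) {
  int N = coords.nrow();
  double best = 1e30;
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      if (mol_id[i] == mol_id[j]) continue;
      double dx = mimg(coords(i, 0) - coords(j, 0), L);
      double dy = mimg(coords(i, 1) - coords(j, 1), L);
      double dz = mimg(coords(i, 2) - coords(j, 2), L);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < best) best = r2;
    }
  return std::sqrt(best);
}

// greedy overlap-removal: rigid translations/rotations accepted when they do
// not increase the soft-core overlap penalty sum((dmin - r)^2, r < dmin).
// Molecule pairs are pre-screened by centre distance.
// [[Rcpp::export]]
List cpp_pack_relax(NumericMatrix coords, double L, IntegerVector mol_start,
                    IntegerVector mol_len, double dmin, int max_sweeps,
                    double seed_u) {
  int nmol = mol_start.size();
  int N = coords.nrow();
  std::vector<double> X(N), Y(N), Z(N);
  for (int i = 0; i < N; ++i) { X[i] = coords(i, 0); Y[i] = coords(i, 1); Z[i] = coords(i, 2); }
  Rng rng((uint64_t)seed_u);
  double d2 = dmin * dmin;

  std::vector<double> CX(nmol), CY(nmol), CZ(nmol), RAD(nmol);
  auto update_geom = [&](int m) {
    int s = mol_start[m], n = mol_len[m];
    double sx = 0, sy = 0, sz = 0;
    for (int i = s; i < s + n; ++i) { sx += X[i]; sy += Y[i]; sz += Z[i]; }
    CX[m] = sx / n; CY[m] = sy / n; CZ[m] = sz / n;
    double r2m = 0;
    for (int i = s; i < s + n; ++i) {
      double dx = X[i] - CX[m], dy = Y[i] - CY[m], dz = Z[i] - CZ[m];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > r2m) r2m = r2;
    }
    RAD[m] = std::sqrt(r2m);
    double wx = std::floor(CX[m] / L) * L, wy = std::floor(CY[m] / L) * L,
           wz = std::floor(CZ[m] / L) * L;
    if (wx != 0 || wy != 0 || wz != 0) {
      for (int i = s; i < s + n; ++i) { X[i] -= wx; Y[i] -= wy; Z[i] -= wz; }
      CX[m] -= wx; CY[m] -= wy; CZ[m] -= wz;
    }
  };
  for (int m = 0; m < nmol; ++m) update_geom(m);

  // penalty of molecule m (optionally with trial coordinates/centre)
  auto mol_pen = [&](int m, const double *tx, const double *ty, const double *tz,
                     double tcx, double tcy, double tcz, double trad) {
    int s = mol_start[m], n = mol_len[m];
    double pen = 0;
    for (int o = 0; o < nmol; ++o) {
      if (o == m) continue;
      double dx = mimg(tcx - CX[o], L), dy = mimg(tcy - CY[o], L), dz = mimg(tcz - CZ[o], L);
      double cut = dmin + trad + RAD[o];
      if (dx * dx + dy * dy + dz * dz > cut * cut) continue;
      int so = mol_start[o], no = mol_len[o];
      for (int a = 0; a < n; ++a) {
        double axp = tx ? tx[a] : X[s + a];
        double ayp = ty ? ty[a] : Y[s + a];
        double azp = tz ? tz[a] : Z[s + a];
        for (int j = so; j < so + no; ++j) {
          double ddx = mimg(axp - X[j], L), ddy = mimg(ayp - Y[j], L), ddz = mimg(azp - Z[j], L);
          double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
          if (r2 < d2) { double d = dmin - std::sqrt(r2); pen += d * d; }
        }
      }
    }
    return pen;
  };

  std::vector<double> tx, ty, tz;
  int sweep;
  for (sweep = 0; sweep < max_sweeps; ++sweep) {
    double tot_pen = 0;
    for (int m = 0; m < nmol; ++m)
      tot_pen += mol_pen(m, nullptr, nullptr, nullptr, CX[m], CY[m], CZ[m], RAD[m]);
    if (tot_pen == 0) break;
    for (int mv = 0; mv < nmol; ++mv) {
      int m = rng.pick(nmol);
      int s = mol_start[m], n = mol_len[m];
      double p_old = mol_pen(m, nullptr, nullptr, nullptr, CX[m], CY[m], CZ[m], RAD[m]);
      if (p_old == 0) continue;
      tx.assign(X.begin() + s, X.begin() + s + n);
      ty.assign(Y.begin() + s, Y.begin() + s + n);
      tz.assign(Z.begin() + s, Z.begin() + s + n);
      double trad = RAD[m];
      if (rng.unif() < 0.7 || n == 1) {
        double h = 0.3 + 0.7 * rng.unif();
        double dx = rng.sym(h), dy = rng.sym(h), dz = rng.sym(h);
        for (int i = 0; i < n; ++i) { tx[i] += dx; ty[i] += dy; tz[i] += dz; }
      } else {
        double ux, uy, uz; rand_axis(rng, ux, uy, uz);
        double ang = rng.sym(1.0);
        double c = std::cos(ang), sn = std::sin(ang);
        for (int i = 0; i < n; ++i) {
          double px = tx[i] - CX[m], py = ty[i] - CY[m], pz = tz[i] - CZ[m];
          rodrigues(px, py, pz, ux, uy, uz, c, sn);
          tx[i] = px + CX[m]; ty[i] = py + CY[m]; tz[i] = pz + CZ[m];
        }
      }
      double tcx = 0, tcy = 0, tcz = 0;
      for (int i = 0; i < n; ++i) { tcx += tx[i]; tcy += ty[i]; tcz += tz[i]; }
      tcx /= n; tcy /= n; tcz /= n;
      double p_new = mol_pen(m, tx.data(), ty.data(), tz.data(), tcx, tcy, tcz, trad);
      if (p_new <= p_old) {
        for (int i = 0; i < n; ++i) { X[s + i] = tx[i]; Y[s + i] = ty[i]; Z[s + i] = tz[i]; }
        update_geom(m);
      }
    }
    if ((sweep & 7) == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix out(N, 3);
  for (int i = 0; i < N; ++i) { out(i, 0) = X[i]; out(i, 1) = Y[i]; out(i, 2) = Z[i]; }
  return List::create(_["coords"] = out, _["sweeps"] = sweep);
}
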