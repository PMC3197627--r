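// Coarse-grained MD kernels: force-shifted nonbonded terms, bonded terms,
// cell-list neighbour search, leapfrog integration with Berendsen coupling.
// Units: A, ps, amu, kJ/mol, bar, elementary charge.
// Coordinates/forces use an interleaved layout (p[3i+d]) so a pair access
// touches one cache line per bead.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// unit conversions
static const double ACC_FAC = 100.0;    // (kJ/mol/A)/amu -> A/ps^2
static const double KE_FAC  = 0.01;     // amu*(A/ps)^2 -> kJ/mol
static const double KB      = 0.0083144621; // kJ/mol/K
static const double PRESFAC = 16605.39; // kJ/mol/A^3 -> bar

struct ShiftConst { double A, B, C; };

// GROMACS-style force-shift constants for a 1/r^p term, shifted over [r1, rc]
static ShiftConst shift_const(int p, double r1, double rc) {
  ShiftConst s;
  double d = rc - r1;
  s.A = -p * ((p + 4) * rc - (p + 1) * r1) / (std::pow(rc, p + 2) * d * d);
  s.B =  p * ((p + 3) * rc - (p + 1) * r1) / (std::pow(rc, p + 2) * d * d * d);
  s.C = 1.0 / std::pow(rc, p) - (s.A / 3.0) * d * d * d - (s.B / 4.0) * d * d * d * d;
  return s;
}

static inline double mi2(double dx, double L, double invL) {
  return dx - L * std::nearbyint(dx * invL);
}

struct Topology {
  std::vector<int> type;            // 0-based
  std::vector<double> charge, mass;
  std::vector<int> bi, bj; std::vector<double> b0, kb;
  std::vector<int> ai, aj, ak; std::vector<double> cth0, kang;
  std::vector<int> di, dj, dk, dl; std::vector<double> phi0, kdih;
  std::vector<std::vector<int>> excl;   // sorted adjacency (both directions)
  int ntype;
  std::vector<double> c6, c12;          // ntype*ntype
  double r1lj, rc, felec;
  ShiftConst s6, s12, s1;
  bool any_charge;
};

static Topology make_topology(const IntegerVector &type, const NumericVector &charge,
                              const NumericVector &mass,
                              const NumericMatrix &epsmat, const NumericMatrix &sigmat,
                              double r1lj, double rc, double felec,
                              const IntegerMatrix &bonds, const NumericVector &b0,
                              const NumericVector &kb,
                              const IntegerMatrix &angles, const NumericVector &th0,
                              const NumericVector &ka,
                              const IntegerMatrix &dihs, const NumericVector &phi0,
                              const NumericVector &kd,
                              const IntegerMatrix &excl) {
  Topology T;
  int n = type.size();
  T.type.assign(type.begin(), type.end());
  T.charge.assign(charge.begin(), charge.end());
  T.mass.assign(mass.begin(), mass.end());
  T.ntype = epsmat.nrow();
  T.c6.resize(T.ntype * T.ntype); T.c12.resize(T.ntype * T.ntype);
  for (int a = 0; a < T.ntype; ++a)
    for (int b = 0; b < T.ntype; ++b) {
      double eps = epsmat(a, b), sig = sigmat(a, b);
      double s6 = std::pow(sig, 6);
      T.c6[a * T.ntype + b]  = 4.0 * eps * s6;
      T.c12[a * T.ntype + b] = 4.0 * eps * s6 * s6;
    }
  T.r1lj = r1lj; T.rc = rc; T.felec = felec;
  T.s6 = shift_const(6, r1lj, rc);
  T.s12 = shift_const(12, r1lj, rc);
  T.s1 = shift_const(1, 0.0, rc);
  T.any_charge = false;
  for (int i = 0; i < n; ++i) if (charge[i] != 0.0) T.any_charge = true;
  for (int r = 0; r < bonds.nrow(); ++r) { T.bi.push_back(bonds(r,0)); T.bj.push_back(bonds(r,1)); }
  T.b0.assign(b0.begin(), b0.end()); T.kb.assign(kb.begin(), kb.end());
  for (int r = 0; r < angles.nrow(); ++r) { T.ai.push_back(angles(r,0)); T.aj.push_back(angles(r,1)); T.ak.push_back(angles(r,2)); }
  for (int r = 0; r < th0.size(); ++r) T.cth0.push_back(std::cos(th0[r] * M_PI / 180.0));
  T.kang.assign(ka.begin(), ka.end());
  for (int r = 0; r < dihs.nrow(); ++r) { T.di.push_back(dihs(r,0)); T.dj.push_back(dihs(r,1)); T.dk.push_back(dihs(r,2)); T.dl.push_back(dihs(r,3)); }
  for (int r = 0; r < phi0.size(); ++r) T.phi0.push_back(phi0[r] * M_PI / 180.0);
  T.kdih.assign(kd.begin(), kd.end());
  T.excl.assign(n, std::vector<int>());
  for (int r = 0; r < excl.nrow(); ++r) {
    T.excl[excl(r,0)].push_back(excl(r,1));
    T.excl[excl(r,1)].push_back(excl(r,0));
  }
  for (int i = 0; i < n; ++i) std::sort(T.excl[i].begin(), T.excl[i].end());
  return T;
}

static inline bool is_excluded(const Topology &T, int i, int j) {
  const std::vector<int> &e = T.excl[i];
  return std::binary_search(e.begin(), e.end(), j);
}

// ---- neighbour list ----------------------------------------------------

struct PairList {
  std::vector<int> i, j;
  std::vector<double> c6, c12, qq;   // per-pair coefficients (when built with T)
};

static void build_pairs_idx(const std::vector<double> &P, int n, const double box[3],
                            double rl, const Topology *T, PairList &PL) {
  std::vector<int> &pi = PL.i, &pj = PL.j;
  pi.clear(); pj.clear();
  double rl2 = rl * rl;
  const double ibx = 1.0 / box[0], iby = 1.0 / box[1], ibz = 1.0 / box[2];
  // finer cells (edge >= rl/2); fall back to all-pairs when the stencil
  // could wrap onto itself (small boxes)
  int nc[3], rng[3];
  bool cellok = true;
  for (int d = 0; d < 3; ++d) {
    nc[d] = std::max(1, (int)std::floor(box[d] / (rl / 2.0)));
    rng[d] = (int)std::ceil(rl / (box[d] / nc[d]));
    if (nc[d] <= 2 * rng[d]) cellok = false;
  }
  if (!cellok || n < 400) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = mi2(P[3*i]-P[3*j], box[0], ibx);
        double dy = mi2(P[3*i+1]-P[3*j+1], box[1], iby);
        double dz = mi2(P[3*i+2]-P[3*j+2], box[2], ibz);
        if (dx*dx + dy*dy + dz*dz <= rl2) {
          if (T && is_excluded(*T, i, j)) continue;
          pi.push_back(i); pj.push_back(j);
        }
      }
    return;
  }
  int ncell = nc[0] * nc[1] * nc[2];
  std::vector<int> count(ncell, 0), start(ncell + 1, 0), order(n), cell(n);
  for (int i = 0; i < n; ++i) {
    double xi = P[3*i]   - box[0] * std::floor(P[3*i]   * ibx);
    double yi = P[3*i+1] - box[1] * std::floor(P[3*i+1] * iby);
    double zi = P[3*i+2] - box[2] * std::floor(P[3*i+2] * ibz);
    int a = std::min(nc[0]-1, (int)(xi * ibx * nc[0]));
    int b = std::min(nc[1]-1, (int)(yi * iby * nc[1]));
    int c = std::min(nc[2]-1, (int)(zi * ibz * nc[2]));
    cell[i] = (a * nc[1] + b) * nc[2] + c;
    ++count[cell[i]];
  }
  for (int c = 0; c < ncell; ++c) start[c + 1] = start[c] + count[c];
  {
    std::vector<int> fill(start.begin(), start.end() - 1);
    for (int i = 0; i < n; ++i) order[fill[cell[i]]++] = i;
  }
  pi.reserve((size_t)n * 40); pj.reserve((size_t)n * 40);
  std::vector<std::array<int,3>> offs;
  for (int da = -rng[0]; da <= rng[0]; ++da)
    for (int db = -rng[1]; db <= rng[1]; ++db)
      for (int dc = -rng[2]; dc <= rng[2]; ++dc) {
        if (da > 0 || (da == 0 && (db > 0 || (db == 0 && dc > 0))))
          offs.push_back({da, db, dc});
      }
  for (int a = 0; a < nc[0]; ++a)
    for (int b = 0; b < nc[1]; ++b)
      for (int c = 0; c < nc[2]; ++c) {
        int idx = (a * nc[1] + b) * nc[2] + c;
        int s0 = start[idx], e0 = start[idx + 1];
        if (s0 == e0) continue;
        for (int u = s0; u < e0; ++u)
          for (int v = u + 1; v < e0; ++v) {
            int i = order[u], j = order[v];
            double dx = mi2(P[3*i]-P[3*j], box[0], ibx);
            double dy = mi2(P[3*i+1]-P[3*j+1], box[1], iby);
            double dz = mi2(P[3*i+2]-P[3*j+2], box[2], ibz);
            if (dx*dx + dy*dy + dz*dz <= rl2) {
              if (T && is_excluded(*T, std::min(i,j), std::max(i,j))) continue;
              pi.push_back(std::min(i,j)); pj.push_back(std::max(i,j));
            }
          }
        for (const auto &o : offs) {
          int a2 = (a + o[0] + nc[0]) % nc[0];
          int b2 = (b + o[1] + nc[1]) % nc[1];
          int c2 = (c + o[2] + nc[2]) % nc[2];
          int jdx = (a2 * nc[1] + b2) * nc[2] + c2;
          int s1 = start[jdx], e1 = start[jdx + 1];
          for (int u = s0; u < e0; ++u) {
            int i = order[u];
            const double xi = P[3*i], yi = P[3*i+1], zi = P[3*i+2];
            for (int v = s1; v < e1; ++v) {
              int j = order[v];
              double dx = mi2(xi-P[3*j], box[0], ibx);
              double dy = mi2(yi-P[3*j+1], box[1], iby);
              double dz = mi2(zi-P[3*j+2], box[2], ibz);
              if (dx*dx + dy*dy + dz*dz <= rl2) {
                if (T && is_excluded(*T, std::min(i,j), std::max(i,j))) continue;
                pi.push_back(std::min(i,j)); pj.push_back(std::max(i,j));
              }
            }
          }
        }
      }
}

static void build_pairs(const std::vector<double> &P, int n, const double box[3],
                        double rl, const Topology *T, PairList &PL) {
  build_pairs_idx(P, n, box, rl, T, PL);
  if (T) {
    size_t np = PL.i.size();
    PL.c6.resize(np); PL.c12.resize(np); PL.qq.resize(np);
    for (size_t p = 0; p < np; ++p) {
      int i = PL.i[p], j = PL.j[p];
      int idx = T->type[i] * T->ntype + T->type[j];
      PL.c6[p] = T->c6[idx]; PL.c12[p] = T->c12[idx];
      PL.qq[p] = T->charge[i] * T->charge[j];
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_pair_list(NumericMatrix xyz, NumericVector box, double rcut) {
  int n = xyz.nrow();
  double bx[3] = {box[0], box[1], box[2]};
  for (int d = 0; d < 3; ++d)
    if (bx[d] < 2.0 * rcut) stop("box too small for cutoff: length %f < 2*%f", bx[d], rcut);
  std::vector<double> P(3 * n);
  for (int i = 0; i < n; ++i) { P[3*i]=xyz(i,0); P[3*i+1]=xyz(i,1); P[3*i+2]=xyz(i,2); }
  PairList PL;
  build_pairs(P, n, bx, rcut, nullptr, PL);
  IntegerMatrix out(PL.i.size(), 2);
  for (size_t r = 0; r < PL.i.size(); ++r) { out(r,0) = PL.i[r]+1; out(r,1) = PL.j[r]+1; }
  return out;
}

// ---- forces ------------------------------------------------------------

struct Energies {
  double lj = 0, coul = 0, bond = 0, angle = 0, dih = 0;
  double vir[3] = {0, 0, 0};  // diagonal virial sum r_a * f_a (kJ/mol)
};

static void compute_forces_core(const std::vector<double> &P, int n, const double box[3],
                                const Topology &T, const PairList &PL,
                                std::vector<double> &F, Energies &E,
                                bool need_energy = true, bool need_virial = true) {
  std::fill(F.begin(), F.end(), 0.0);
  E = Energies();
  double rc2 = T.rc * T.rc;
  const double r1 = T.r1lj;
  const double ibx = 1.0 / box[0], iby = 1.0 / box[1], ibz = 1.0 / box[2];
  const double bx_ = box[0], by_ = box[1], bz_ = box[2];
  const double A3_6 = T.s6.A / 3.0, B4_6 = T.s6.B / 4.0;
  const double A3_12 = T.s12.A / 3.0, B4_12 = T.s12.B / 4.0;
  const size_t npair = PL.i.size();
  const int *pi = PL.i.data();
  const int *pj = PL.j.data();
  const double *pc6 = PL.c6.data();
  const double *pc12 = PL.c12.data();
  const double *pqq = PL.qq.data();
  // pass 1: minimum-image separations, compact to pairs inside the cutoff
  static thread_local std::vector<double> vdx, vdy, vdz, vr2, vinv, vinv2;
  static thread_local std::vector<int> vsel;
  if (vdx.size() < npair) {
    vdx.resize(npair); vdy.resize(npair); vdz.resize(npair);
    vr2.resize(npair); vinv.resize(npair); vinv2.resize(npair);
    vsel.resize(npair);
  }
  size_t m = 0;
  for (size_t p = 0; p < npair; ++p) {
    int i = pi[p], j = pj[p];
    double dx = mi2(P[3*i]-P[3*j], bx_, ibx);
    double dy = mi2(P[3*i+1]-P[3*j+1], by_, iby);
    double dz = mi2(P[3*i+2]-P[3*j+2], bz_, ibz);
    double r2 = dx*dx + dy*dy + dz*dz;
    if (r2 >= rc2) continue;
    if (r2 < 0.01)
      stop("overlapping beads %d and %d (r < 0.1 A)", pi[p] + 1, pj[p] + 1);
    vdx[m] = dx; vdy[m] = dy; vdz[m] = dz; vr2[m] = r2; vsel[m] = (int)p;
    ++m;
  }
  // pass 2: reciprocal and square root as vectorizable array sweeps
  for (size_t k = 0; k < m; ++k) vinv2[k] = 1.0 / vr2[k];
  for (size_t k = 0; k < m; ++k) vinv[k] = std::sqrt(vinv2[k]);
  // pass 3: forces
  for (size_t k = 0; k < m; ++k) {
    size_t p = (size_t)vsel[k];
    int i = pi[p], j = pj[p];
    double dx = vdx[k], dy = vdy[k], dz = vdz[k];
    double r2 = vr2[k], inv2 = vinv2[k], inv = vinv[k];
    double r = r2 * inv;
    double inv6 = inv2 * inv2 * inv2, inv12 = inv6 * inv6;
    const double c6 = pc6[p], c12 = pc12[p];
    double f6 = 6.0 * inv6 * inv, f12 = 12.0 * inv12 * inv;
    if (r > r1) {
      double d = r - r1, d2 = d * d, d3 = d2 * d;
      f6  += T.s6.A * d2 + T.s6.B * d3;
      f12 += T.s12.A * d2 + T.s12.B * d3;
    }
    double fr = c12 * f12 - c6 * f6;   // -dV/dr
    if (need_energy) {
      double p6 = inv6 - T.s6.C, p12 = inv12 - T.s12.C;
      if (r > r1) {
        double d = r - r1, d3 = d * d * d, d4 = d3 * d;
        p6  -= A3_6 * d3 + B4_6 * d4;
        p12 -= A3_12 * d3 + B4_12 * d4;
      }
      E.lj += c12 * p12 - c6 * p6;
    }
    {
      double qq = pqq[p];
      if (qq != 0.0) {
        double d2 = r2, d3 = d2 * r, d4 = d3 * r;  // r1 = 0 for Coulomb
        double f1 = inv2 + T.s1.A * d2 + T.s1.B * d3;
        fr += T.felec * qq * f1;
        if (need_energy)
          E.coul += T.felec * qq *
            (inv - (T.s1.A / 3.0) * d3 - (T.s1.B / 4.0) * d4 - T.s1.C);
      }
    }
    double fscale = fr * inv;
    double fxp = fscale * dx, fyp = fscale * dy, fzp = fscale * dz;
    F[3*i] += fxp; F[3*i+1] += fyp; F[3*i+2] += fzp;
    F[3*j] -= fxp; F[3*j+1] -= fyp; F[3*j+2] -= fzp;
    if (need_virial) {
      E.vir[0] += fxp * dx; E.vir[1] += fyp * dy; E.vir[2] += fzp * dz;
    }
  }
  // bonds
  for (size_t b = 0; b < T.bi.size(); ++b) {
    int i = T.bi[b], j = T.bj[b];
    double dx = mi2(P[3*i]-P[3*j], bx_, ibx);
    double dy = mi2(P[3*i+1]-P[3*j+1], by_, iby);
    double dz = mi2(P[3*i+2]-P[3*j+2], bz_, ibz);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double dr = r - T.b0[b];
    E.bond += 0.5 * T.kb[b] * dr * dr;
    double fscale = -T.kb[b] * dr / r;
    double fxp = fscale * dx, fyp = fscale * dy, fzp = fscale * dz;
    F[3*i] += fxp; F[3*i+1] += fyp; F[3*i+2] += fzp;
    F[3*j] -= fxp; F[3*j+1] -= fyp; F[3*j+2] -= fzp;
    E.vir[0] += fxp * dx; E.vir[1] += fyp * dy; E.vir[2] += fzp * dz;
  }
  // angles: cosine-harmonic V = 0.5 ka (cos t - cos t0)^2
  for (size_t a = 0; a < T.ai.size(); ++a) {
    int i = T.ai[a], j = T.aj[a], k = T.ak[a];
    double ux = mi2(P[3*i]-P[3*j], bx_, ibx), uy = mi2(P[3*i+1]-P[3*j+1], by_, iby),
           uz = mi2(P[3*i+2]-P[3*j+2], bz_, ibz);
    double vx = mi2(P[3*k]-P[3*j], bx_, ibx), vy = mi2(P[3*k+1]-P[3*j+1], by_, iby),
           vz = mi2(P[3*k+2]-P[3*j+2], bz_, ibz);
    double nu = std::sqrt(ux*ux + uy*uy + uz*uz), nv = std::sqrt(vx*vx + vy*vy + vz*vz);
    double ct = (ux*vx + uy*vy + uz*vz) / (nu * nv);
    ct = std::max(-1.0, std::min(1.0, ct));
    double dct = ct - T.cth0[a];
    E.angle += 0.5 * T.kang[a] * dct * dct;
    double pref = -T.kang[a] * dct;  // -dV/dcos
    double gix = pref * (vx / (nu*nv) - ct * ux / (nu*nu));
    double giy = pref * (vy / (nu*nv) - ct * uy / (nu*nu));
    double giz = pref * (vz / (nu*nv) - ct * uz / (nu*nu));
    double gkx = pref * (ux / (nu*nv) - ct * vx / (nv*nv));
    double gky = pref * (uy / (nu*nv) - ct * vy / (nv*nv));
    double gkz = pref * (uz / (nu*nv) - ct * vz / (nv*nv));
    F[3*i] += gix; F[3*i+1] += giy; F[3*i+2] += giz;
    F[3*k] += gkx; F[3*k+1] += gky; F[3*k+2] += gkz;
    F[3*j] -= gix + gkx; F[3*j+1] -= giy + gky; F[3*j+2] -= giz + gkz;
    E.vir[0] += gix * ux + gkx * vx;
    E.vir[1] += giy * uy + gky * vy;
    E.vir[2] += giz * uz + gkz * vz;
  }
  // dihedral restraints: V = 0.5 kd wrap(phi - phi0)^2
  for (size_t d = 0; d < T.di.size(); ++d) {
    int i = T.di[d], j = T.dj[d], k = T.dk[d], l = T.dl[d];
    double b1x = mi2(P[3*j]-P[3*i], bx_, ibx), b1y = mi2(P[3*j+1]-P[3*i+1], by_, iby),
           b1z = mi2(P[3*j+2]-P[3*i+2], bz_, ibz);
    double b2x = mi2(P[3*k]-P[3*j], bx_, ibx), b2y = mi2(P[3*k+1]-P[3*j+1], by_, iby),
           b2z = mi2(P[3*k+2]-P[3*j+2], bz_, ibz);
    double b3x = mi2(P[3*l]-P[3*k], bx_, ibx), b3y = mi2(P[3*l+1]-P[3*k+1], by_, iby),
           b3z = mi2(P[3*l+2]-P[3*k+2], bz_, ibz);
    double n1x = b1y*b2z - b1z*b2y, n1y = b1z*b2x - b1x*b2z, n1z = b1x*b2y - b1y*b2x;
    double n2x = b2y*b3z - b2z*b3y, n2y = b2z*b3x - b2x*b3z, n2z = b2x*b3y - b2y*b3x;
    double n1sq = n1x*n1x + n1y*n1y + n1z*n1z;
    double n2sq = n2x*n2x + n2y*n2y + n2z*n2z;
    double nb2 = std::sqrt(b2x*b2x + b2y*b2y + b2z*b2z);
    if (n1sq < 1e-12 || n2sq < 1e-12) continue;
    double mx = n1y*n2z - n1z*n2y, my = n1z*n2x - n1x*n2z, mz = n1x*n2y - n1y*n2x;
    double sinp = (mx*b2x + my*b2y + mz*b2z) / nb2;
    double cosp = n1x*n2x + n1y*n2y + n1z*n2z;
    double phi = std::atan2(sinp, cosp);
    double dphi = phi - T.phi0[d];
    while (dphi > M_PI) dphi -= 2.0 * M_PI;
    while (dphi <= -M_PI) dphi += 2.0 * M_PI;
    E.dih += 0.5 * T.kdih[d] * dphi * dphi;
    double dVdphi = T.kdih[d] * dphi;
    double gix = -nb2 / n1sq * n1x, giy = -nb2 / n1sq * n1y, giz = -nb2 / n1sq * n1z;
    double glx =  nb2 / n2sq * n2x, gly =  nb2 / n2sq * n2y, glz =  nb2 / n2sq * n2z;
    double c1 = (b1x*b2x + b1y*b2y + b1z*b2z) / (nb2 * nb2);
    double c2 = (b3x*b2x + b3y*b2y + b3z*b2z) / (nb2 * nb2);
    double gjx = -(1.0 + c1) * gix + c2 * glx;
    double gjy = -(1.0 + c1) * giy + c2 * gly;
    double gjz = -(1.0 + c1) * giz + c2 * glz;
    double gkx = -gix - gjx - glx;
    double gky = -giy - gjy - gly;
    double gkz = -giz - gjz - glz;
    double Fi[3] = {-dVdphi*gix, -dVdphi*giy, -dVdphi*giz};
    double Fj[3] = {-dVdphi*gjx, -dVdphi*gjy, -dVdphi*gjz};
    double Fk[3] = {-dVdphi*gkx, -dVdphi*gky, -dVdphi*gkz};
    double Fl[3] = {-dVdphi*glx, -dVdphi*gly, -dVdphi*glz};
    F[3*i] += Fi[0]; F[3*i+1] += Fi[1]; F[3*i+2] += Fi[2];
    F[3*j] += Fj[0]; F[3*j+1] += Fj[1]; F[3*j+2] += Fj[2];
    F[3*k] += Fk[0]; F[3*k+1] += Fk[1]; F[3*k+2] += Fk[2];
    F[3*l] += Fl[0]; F[3*l+1] += Fl[1]; F[3*l+2] += Fl[2];
    double ri[3] = {-b1x, -b1y, -b1z};
    double rk[3] = {b2x, b2y, b2z};
    double rl_[3] = {b2x + b3x, b2y + b3y, b2z + b3z};
    E.vir[0] += Fi[0]*ri[0] + Fk[0]*rk[0] + Fl[0]*rl_[0];
    E.vir[1] += Fi[1]*ri[1] + Fk[1]*rk[1] + Fl[1]*rl_[1];
    E.vir[2] += Fi[2]*ri[2] + Fk[2]*rk[2] + Fl[2]*rl_[2];
  }
}

static std::vector<double> flatten(const NumericMatrix &m) {
  int n = m.nrow();
  std::vector<double> P(3 * n);
  for (int i = 0; i < n; ++i) { P[3*i]=m(i,0); P[3*i+1]=m(i,1); P[3*i+2]=m(i,2); }
  return P;
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix xyz, NumericVector box,
                IntegerVector type, NumericVector charge, NumericVector mass,
                NumericMatrix epsmat, NumericMatrix sigmat,
                double r1lj, double rc, double felec,
                IntegerMatrix bonds, NumericVector b0, NumericVector kb,
                IntegerMatrix angles, NumericVector th0, NumericVector ka,
                IntegerMatrix dihs, NumericVector phi0, NumericVector kd,
                IntegerMatrix excl) {
  int n = xyz.nrow();
  Topology T = make_topology(type, charge, mass, epsmat, sigmat, r1lj, rc, felec,
                             bonds, b0, kb, angles, th0, ka, dihs, phi0, kd, excl);
  std::vector<double> P = flatten(xyz), F(3 * n);
  double bx[3] = {box[0], box[1], box[2]};
  PairList PL;
  build_pairs(P, n, bx, rc, &T, PL);
  Energies E;
  compute_forces_core(P, n, bx, T, PL, F, E);
  NumericMatrix Fm(n, 3);
  for (int i = 0; i < n; ++i) { Fm(i,0)=F[3*i]; Fm(i,1)=F[3*i+1]; Fm(i,2)=F[3*i+2]; }
  return List::create(_["forces"] = Fm,
                      _["lj"] = E.lj, _["coulomb"] = E.coul, _["bond"] = E.bond,
                      _["angle"] = E.angle, _["dihedral"] = E.dih,
                      _["virial"] = NumericVector::create(E.vir[0], E.vir[1], E.vir[2]));
}

// [[Rcpp::export]]
List cpp_run_md(NumericMatrix xyz, NumericMatrix vel, NumericVector box,
                IntegerVector type, NumericVector charge, NumericVector mass,
                NumericMatrix epsmat, NumericMatrix sigmat,
                double r1lj, double rc, double felec,
                IntegerMatrix bonds, NumericVector b0, NumericVector kb,
                IntegerMatrix angles, NumericVector th0, NumericVector ka,
                IntegerMatrix dihs, NumericVector phi0, NumericVector kd,
                IntegerMatrix excl,
                int nsteps, double dt,
                bool thermo, double tref, double taut,
                bool baro, double pref, double taup, double kappa,
                int nlist_every, double skin, int com_every,
                int sample_every, int frame_every, double t0) {
  int n = xyz.nrow();
  Topology T = make_topology(type, charge, mass, epsmat, sigmat, r1lj, rc, felec,
                             bonds, b0, kb, angles, th0, ka, dihs, phi0, kd, excl);
  std::vector<double> P = flatten(xyz), V = flatten(vel), F(3 * n);
  double bx[3] = {box[0], box[1], box[2]};
  for (int d = 0; d < 3; ++d)
    if (bx[d] <= 2.0 * rc) stop("box length %f must exceed 2*r_cut = %f", bx[d], 2.0*rc);
  int ndf = 3 * n - 3;
  double totmass = 0; for (int i = 0; i < n; ++i) totmass += T.mass[i];
  PairList PL;
  Energies E;
  int nsample = sample_every > 0 ? nsteps / sample_every + 1 : 0;
  NumericMatrix samples(std::max(nsample, 1), 16);
  int srow = 0;
  List frames; std::vector<double> ftime;
  std::vector<std::array<double,3>> fbox_store;
  for (int step = 0; step < nsteps; ++step) {
    if (step % nlist_every == 0) {
      for (int i = 0; i < 3 * n; ++i) {
        if (!std::isfinite(P[i]))
          stop("non-finite coordinate for bead %d at step %d", i / 3 + 1, step);
        int d = i % 3;
        P[i] -= bx[d] * std::floor(P[i] / bx[d]);
      }
      build_pairs(P, n, bx, rc + skin, &T, PL);
    }
    const int pcouple_every = 10;
    bool sampling = sample_every > 0 && step % sample_every == 0;
    bool coupling = baro && step % pcouple_every == 0;
    compute_forces_core(P, n, bx, T, PL, F, E, sampling, sampling || coupling);
    // kinetic energy from half-step velocities
    double kex = 0, key = 0, kez = 0;
    for (int i = 0; i < n; ++i) {
      kex += T.mass[i] * V[3*i] * V[3*i];
      key += T.mass[i] * V[3*i+1] * V[3*i+1];
      kez += T.mass[i] * V[3*i+2] * V[3*i+2];
    }
    double ke = 0.5 * KE_FAC * (kex + key + kez);
    double tinst = 2.0 * ke / (ndf * KB);
    if (sampling && srow < nsample) {
      double vol = bx[0] * bx[1] * bx[2];
      double pxx = (KE_FAC * kex + E.vir[0]) / vol * PRESFAC;
      double pyy = (KE_FAC * key + E.vir[1]) / vol * PRESFAC;
      double pzz = (KE_FAC * kez + E.vir[2]) / vol * PRESFAC;
      double epot = E.lj + E.coul + E.bond + E.angle + E.dih;
      samples(srow, 0) = t0 + step * dt;
      samples(srow, 1) = E.lj;  samples(srow, 2) = E.coul;
      samples(srow, 3) = E.bond; samples(srow, 4) = E.angle; samples(srow, 5) = E.dih;
      samples(srow, 6) = epot;  samples(srow, 7) = ke; samples(srow, 8) = epot + ke;
      samples(srow, 9) = tinst;
      samples(srow, 10) = pxx; samples(srow, 11) = pyy; samples(srow, 12) = pzz;
      samples(srow, 13) = bx[0]; samples(srow, 14) = bx[1]; samples(srow, 15) = bx[2];
      ++srow;
    }
    // leapfrog with Berendsen velocity scaling
    double lambda = 1.0;
    if (thermo && tinst > 1e-10) {
      lambda = std::sqrt(1.0 + dt / taut * (tref / tinst - 1.0));
      lambda = std::max(0.8, std::min(1.25, lambda));
    }
    for (int i = 0; i < n; ++i) {
      double am = ACC_FAC * dt / T.mass[i];
      V[3*i]   = lambda * (V[3*i]   + am * F[3*i]);
      V[3*i+1] = lambda * (V[3*i+1] + am * F[3*i+1]);
      V[3*i+2] = lambda * (V[3*i+2] + am * F[3*i+2]);
      P[3*i] += V[3*i] * dt; P[3*i+1] += V[3*i+1] * dt; P[3*i+2] += V[3*i+2] * dt;
    }
    if (coupling) {
      double vol = bx[0] * bx[1] * bx[2];
      double pxx = (KE_FAC * kex + E.vir[0]) / vol * PRESFAC;
      double pyy = (KE_FAC * key + E.vir[1]) / vol * PRESFAC;
      double pzz = (KE_FAC * kez + E.vir[2]) / vol * PRESFAC;
      double plat = 0.5 * (pxx + pyy);
      double dtc = dt * pcouple_every;
      double mulat = std::cbrt(1.0 - dtc / taup * kappa * (pref - plat));
      double muz   = std::cbrt(1.0 - dtc / taup * kappa * (pref - pzz));
      mulat = std::max(0.995, std::min(1.005, mulat));
      muz   = std::max(0.995, std::min(1.005, muz));
      for (int i = 0; i < n; ++i) {
        P[3*i] *= mulat; P[3*i+1] *= mulat; P[3*i+2] *= muz;
      }
      bx[0] *= mulat; bx[1] *= mulat; bx[2] *= muz;
    }
    if (com_every > 0 && step % com_every == 0) {
      double px = 0, py = 0, pz = 0;
      for (int i = 0; i < n; ++i) {
        px += T.mass[i]*V[3*i]; py += T.mass[i]*V[3*i+1]; pz += T.mass[i]*V[3*i+2];
      }
      px /= totmass; py /= totmass; pz /= totmass;
      for (int i = 0; i < n; ++i) { V[3*i] -= px; V[3*i+1] -= py; V[3*i+2] -= pz; }
    }
    if (frame_every > 0 && (step + 1) % frame_every == 0) {
      NumericMatrix fr(n, 3);
      for (int i = 0; i < n; ++i) {
        fr(i,0) = P[3*i]   - bx[0] * std::floor(P[3*i]   / bx[0]);
        fr(i,1) = P[3*i+1] - bx[1] * std::floor(P[3*i+1] / bx[1]);
        fr(i,2) = P[3*i+2] - bx[2] * std::floor(P[3*i+2] / bx[2]);
      }
      frames.push_back(fr);
      ftime.push_back(t0 + (step + 1) * dt);
      fbox_store.push_back({bx[0], bx[1], bx[2]});
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix xout(n, 3), vout(n, 3);
  for (int i = 0; i < n; ++i) {
    xout(i,0) = P[3*i]   - bx[0] * std::floor(P[3*i]   / bx[0]);
    xout(i,1) = P[3*i+1] - bx[1] * std::floor(P[3*i+1] / bx[1]);
    xout(i,2) = P[3*i+2] - bx[2] * std::floor(P[3*i+2] / bx[2]);
    vout(i,0)=V[3*i]; vout(i,1)=V[3*i+1]; vout(i,2)=V[3*i+2];
  }
  NumericMatrix fb(fbox_store.size(), 3);
  for (size_t r = 0; r < fbox_store.size(); ++r)
    for (int d = 0; d < 3; ++d) fb(r, d) = fbox_store[r][d];
  if (nsample > 0 && srow < nsample) samples = samples(Range(0, std::max(0, srow - 1)), _);
  colnames(samples) = CharacterVector::create("time","lj","coulomb","bond","angle",
    "dihedral","epot","ekin","etot","temperature","Pxx","Pyy","Pzz","Lx","Ly","Lz");
  return List::create(_["xyz"] = xout, _["vel"] = vout,
                      _["box"] = NumericVector::create(bx[0], bx[1], bx[2]),
                      _["energies"] = samples,
                      _["frames"] = frames, _["frame_time"] = wrap(ftime),
                      _["frame_box"] = fb);
}

// [[Rcpp::export]]
List cpp_minimize(NumericMatrix xyz, NumericVector box,
                  IntegerVector type, NumericVector charge, NumericVector mass,
                  NumericMatrix epsmat, NumericMatrix sigmat,
                  double r1lj, double rc, double felec,
                  IntegerMatrix bonds, NumericVector b0, NumericVector kb,
                  IntegerMatrix angles, NumericVector th0, NumericVector ka,
                  IntegerMatrix dihs, NumericVector phi0, NumericVector kd,
                  IntegerMatrix excl,
                  int nsteps, double fmax_tol, double step0) {
  int n = xyz.nrow();
  Topology T = make_topology(type, charge, mass, epsmat, sigmat, r1lj, rc, felec,
                             bonds, b0, kb, angles, th0, ka, dihs, phi0, kd, excl);
  std::vector<double> P = flatten(xyz), F(3 * n);
  double bx[3] = {box[0], box[1], box[2]};
  PairList PL;
  Energies E;
  double h = step0;
  for (int i = 0; i < 3 * n; ++i)
    if (!std::isfinite(P[i]))
      stop("non-finite coordinate for bead %d", i / 3 + 1);
  build_pairs(P, n, bx, rc + 2.0, &T, PL);
  compute_forces_core(P, n, bx, T, PL, F, E);
  double eprev = E.lj + E.coul + E.bond + E.angle + E.dih;
  int steps_done = 0;
  double fmax = 0;
  for (int it = 0; it < nsteps; ++it) {
    fmax = 0;
    for (int i = 0; i < 3 * n; ++i) fmax = std::max(fmax, std::abs(F[i]));
    if (fmax < fmax_tol) break;
    if (!std::isfinite(fmax) || !std::isfinite(eprev))
      stop("non-finite energy or force during minimization");
    std::vector<double> Pt(P);
    for (int i = 0; i < 3 * n; ++i) Pt[i] += h * F[i] / fmax;
    std::vector<double> Ft(3 * n);
    PairList QL;
    build_pairs(Pt, n, bx, rc + 2.0, &T, QL);
    Energies Et;
    compute_forces_core(Pt, n, bx, T, QL, Ft, Et);
    double enew = Et.lj + Et.coul + Et.bond + Et.angle + Et.dih;
    if (enew < eprev) {
      P.swap(Pt); F.swap(Ft);
      eprev = enew; h = std::min(h * 1.2, 1.0);
    } else {
      h *= 0.5;
      if (h < 1e-6) break;
    }
    ++steps_done;
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix xout(n, 3);
  for (int i = 0; i < n; ++i) { xout(i,0)=P[3*i]; xout(i,1)=P[3*i+1]; xout(i,2)=P[3*i+2]; }
  return List::create(_["xyz"] = xout, _["energy"] = eprev,
                      _["fmax"] = fmax, _["steps"] = steps_done);
}
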