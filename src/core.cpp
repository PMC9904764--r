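// Coarse-grained MD core: Ashbaugh-Hatch / Kim-Hummer pair potentials,
// Debye-Hueckel electrostatics, harmonic bonds, BAOAB Langevin dynamics
// with quaternion rigid bodies, Verlet neighbor lists, FIRE minimization.
//
// Units (LAMMPS "real" style): length A, time fs, mass g/mol, energy
// kcal/mol, temperature K.  FTM2V converts kcal/mol/A / (g/mol) to A/fs^2.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <unordered_set>

using namespace Rcpp;

static const double FTM2V = 1.0 / 48.88821291 / 48.88821291; // 4.1839e-4
static const double KB = 0.0019872041;                        // kcal/mol/K

// ---------------------------------------------------------------------------
// Deterministic RNG: splitmix64 stream with Marsaglia-Tsang ziggurat
// normals (fast path table lookup; exact Gaussian tails via fallback).

struct ZigTables {
  uint32_t kn[128];
  double wn[128], fn[128];
  ZigTables() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
};
static const ZigTables ZIG;

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { // (0,1)
    return (next() >> 11) * (1.0 / 9007199254740992.0) + 5.0e-17;
  }
  double norm() {
    while (true) {
      int32_t hz = (int32_t)(uint32_t)(next() >> 32);
      uint32_t iz = (uint32_t)hz & 127u;
      uint32_t az = hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
      if (az < ZIG.kn[iz]) return hz * ZIG.wn[iz];
      if (iz == 0) { // tail
        const double r = 3.442619855899;
        double x, y;
        do {
          x = -std::log(unif()) / r;
          y = -std::log(unif());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -(r + x);
      }
      double x = hz * ZIG.wn[iz];
      if (ZIG.fn[iz] + unif() * (ZIG.fn[iz - 1] - ZIG.fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};

// ---------------------------------------------------------------------------
// System container unpacked from the R-side list

static const double CBRT2 = 1.2599210498948732; // (2^{1/6})^2 factor

struct Sys {
  int n, nt;
  std::vector<int> type;         // 0-based type index per bead
  std::vector<double> q, sasa, mass;
  std::vector<double> SIG2v, LAMv, EPSv; // flat nt x nt (column-major)
  double SIG2(int a, int b) const { return SIG2v[a + nt * b]; }
  double LAM(int a, int b) const { return LAMv[a + nt * b]; }
  double EPS(int a, int b) const { return EPSv[a + nt * b]; }
  std::vector<int> b1, b2;       // bonds, 0-based
  double bondR0, bondK;
  std::vector<int> rigid;        // group id per bead, 0 = flexible
  double box;                    // cubic edge, <= 0 means no PBC
  double ke_coul, kappa, dhcut;  // Coulomb const / dielectric, 1/Debye, cutoff
  std::unordered_set<int64_t> excl; // bonded 1-2 exclusions
  double rcutmax2;               // max pair cutoff^2 (AH 3 sigma vs DH)

  bool excluded(int i, int j) const {
    if (rigid[i] != 0 && rigid[i] == rigid[j]) return true;
    int64_t k = (int64_t)std::min(i, j) * n + std::max(i, j);
    return excl.count(k) > 0;
  }
};

static Sys unpack(const List& sys) {
  Sys S;
  S.type = as<std::vector<int>>(sys["type"]);   // already 0-based
  S.n = (int)S.type.size();
  S.q = as<std::vector<double>>(sys["charge"]);
  S.sasa = as<std::vector<double>>(sys["sasa"]);
  S.mass = as<std::vector<double>>(sys["mass"]);
  NumericMatrix sig2 = sys["sig2"], lam = sys["lam"], eps = sys["eps"];
  S.nt = sig2.nrow();
  S.SIG2v.assign(sig2.begin(), sig2.end());
  S.LAMv.assign(lam.begin(), lam.end());
  S.EPSv.assign(eps.begin(), eps.end());
  IntegerMatrix B = sys["bonds"];               // m x 2, 1-based
  for (int k = 0; k < B.nrow(); ++k) {
    S.b1.push_back(B(k, 0) - 1);
    S.b2.push_back(B(k, 1) - 1);
  }
  S.bondR0 = as<double>(sys["bondR0"]);
  S.bondK = as<double>(sys["bondK"]);
  S.rigid = as<std::vector<int>>(sys["rigid"]);
  S.box = as<double>(sys["box"]);
  NumericVector el = sys["elec"];               // ke, debye, cutoff
  S.ke_coul = el[0];
  S.kappa = el[1] > 0 ? 1.0 / el[1] : 0.0;
  S.dhcut = el[2];
  for (size_t k = 0; k < S.b1.size(); ++k) {
    int i = std::min(S.b1[k], S.b2[k]), j = std::max(S.b1[k], S.b2[k]);
    S.excl.insert((int64_t)i * S.n + j);
  }
  double m2 = 0.0;
  for (int a = 0; a < S.nt; ++a)
    for (int b = 0; b < S.nt; ++b)
      m2 = std::max(m2, 9.0 * S.SIG2(a, b)); // (3 sigma)^2
  bool charged = false;
  for (double qq : S.q) if (qq != 0.0) charged = true;
  if (charged) m2 = std::max(m2, S.dhcut * S.dhcut);
  S.rcutmax2 = m2;
  return S;
}

static inline void minimg(double& dx, double& dy, double& dz, double L) {
  if (L > 0) {
    dx -= L * std::nearbyint(dx / L);
    dy -= L * std::nearbyint(dy / L);
    dz -= L * std::nearbyint(dz / L);
  }
}

// Pair interaction (AH + DH) between beads i,j at squared distance r2.
// Adds force on i (fx,fy,fz are the i-j displacement components) and energies.
static inline void pair_kernel(const Sys& S, int i, int j,
                               double dx, double dy, double dz, double r2,
                               double* F, double& e_ah, double& e_dh,
                               bool want_energy) {
  int ti = S.type[i], tj = S.type[j];
  if (r2 < 1e-8) r2 = 1e-8; // coincident beads: keep forces finite
  double s2 = S.SIG2(ti, tj);
  double cut2 = 9.0 * s2;
  double coef = 0.0;
  if (r2 < cut2) {
    double eps = S.EPS(ti, tj) * S.sasa[i] * S.sasa[j];
    double lam = S.LAM(ti, tj);
    double sr2 = s2 / r2;
    double sr6 = sr2 * sr2 * sr2;
    double sr12 = sr6 * sr6;
    double rmin2 = CBRT2 * s2; // (2^{1/6} sigma)^2
    double c = 24.0 * eps * (2.0 * sr12 - sr6) / r2;
    if (r2 <= rmin2) {
      coef += c;
      if (want_energy) e_ah += 4.0 * eps * (sr12 - sr6) + (1.0 - lam) * eps;
    } else {
      coef += lam * c;
      if (want_energy) e_ah += lam * 4.0 * eps * (sr12 - sr6);
    }
  }
  double qq = S.q[i] * S.q[j];
  if (qq != 0.0 && r2 < S.dhcut * S.dhcut) {
    double r = std::sqrt(r2);
    double sc = S.ke_coul * qq * std::exp(-r * S.kappa) / r;
    if (want_energy) e_dh += sc;
    coef += sc * (1.0 / r2 + S.kappa / r);
  }
  if (coef != 0.0) {
    F[3 * i] += coef * dx;  F[3 * i + 1] += coef * dy;  F[3 * i + 2] += coef * dz;
    F[3 * j] -= coef * dx;  F[3 * j + 1] -= coef * dy;  F[3 * j + 2] -= coef * dz;
  }
}

static void bond_forces(const Sys& S, const double* X, double* F,
                        double& e_bond, bool want_energy, double Kscale) {
  double K = S.bondK * Kscale;
  for (size_t k = 0; k < S.b1.size(); ++k) {
    int i = S.b1[k], j = S.b2[k];
    if (S.rigid[i] != 0 && S.rigid[i] == S.rigid[j]) continue; // constrained
    double dx = X[3 * i] - X[3 * j];
    double dy = X[3 * i + 1] - X[3 * j + 1];
    double dz = X[3 * i + 2] - X[3 * j + 2];
    minimg(dx, dy, dz, S.box);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - S.bondR0;
    if (want_energy) e_bond += K * dr * dr;
    double coef = -2.0 * K * dr / r; // U = K (r-r0)^2
    F[3 * i] += coef * dx;  F[3 * i + 1] += coef * dy;  F[3 * i + 2] += coef * dz;
    F[3 * j] -= coef * dx;  F[3 * j + 1] -= coef * dy;  F[3 * j + 2] -= coef * dz;
  }
}

// Full O(N^2) nonbonded loop.
static void nb_forces_full(const Sys& S, const double* X, double* F,
                           double& e_ah, double& e_dh, bool want_energy) {
  for (int i = 0; i < S.n; ++i)
    for (int j = i + 1; j < S.n; ++j) {
      if (S.excluded(i, j)) continue;
      double dx = X[3 * i] - X[3 * j];
      double dy = X[3 * i + 1] - X[3 * j + 1];
      double dz = X[3 * i + 2] - X[3 * j + 2];
      minimg(dx, dy, dz, S.box);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < S.rcutmax2)
        pair_kernel(S, i, j, dx, dy, dz, r2, F, e_ah, e_dh, want_energy);
    }
}

// Verlet pair list with per-pair parameters cached at build time.
struct PairEntry {
  int i, j;
  double s2;      // sigma_ij^2
  double inv_s2;  // 1 / sigma_ij^2
  double rmin2;   // (2^{1/6} sigma)^2
  double lam;     // tail weight
  double eps;     // epsilon_ij * sasa_i * sasa_j
  double qq;      // q_i q_j
  double ahcut2;  // (3 sigma)^2
};

// exp(x) for x in [-8, 0]: range reduction to [-0.25, 0.25] plus a
// degree-9 Taylor polynomial; relative error < 1e-12 on this domain.
static const double EXP_HALF[17] = {
  1.0, 0.6065306597126334, 0.36787944117144233, 0.22313016014842982,
  0.1353352832366127, 0.0820849986238988, 0.049787068367863944,
  0.0301973834223185, 0.01831563888873418, 0.011108996538242306,
  0.006737946999085467, 0.0040867714384640666, 0.0024787521766663585,
  0.0015034391929775724, 0.0009118819655545162, 0.0005530843701478336,
  0.00033546262790251185};
static inline double exp_neg(double x) {
  if (x < -8.0) return std::exp(x); // outside the tabulated domain
  int k = (int)(-x * 2.0 + 0.5);
  double t = x + 0.5 * k;
  double p = 1.0 + t * (1.0 + t * (1.0 / 2) * (1.0 + t * (1.0 / 3) *
             (1.0 + t * (1.0 / 4) * (1.0 + t * (1.0 / 5) *
             (1.0 + t * (1.0 / 6) * (1.0 + t * (1.0 / 7) *
             (1.0 + t * (1.0 / 8) * (1.0 + t * (1.0 / 9)))))))));
  return EXP_HALF[k] * p;
}

// Nonbonded loops over a Verlet pair list split into uncharged (pure
// Ashbaugh-Hatch) and charged (AH + Debye-Hueckel) entries (hot path).
static void nb_forces_uncharged(const Sys& S, const double* X,
                                const std::vector<PairEntry>& plist,
                                double* F, double& e_ah, bool want_energy) {
  const double L = S.box, halfL = 0.5 * S.box;
  for (const PairEntry& p : plist) {
    const int i = p.i, j = p.j;
    double dx = X[3 * i] - X[3 * j];
    double dy = X[3 * i + 1] - X[3 * j + 1];
    double dz = X[3 * i + 2] - X[3 * j + 2];
    if (L > 0) {
      if (dx > halfL) dx -= L; else if (dx < -halfL) dx += L;
      if (dy > halfL) dy -= L; else if (dy < -halfL) dy += L;
      if (dz > halfL) dz -= L; else if (dz < -halfL) dz += L;
    }
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= p.ahcut2) continue;
    if (r2 < 1e-8) r2 = 1e-8; // coincident beads: keep forces finite
    const double sr2 = p.s2 / r2;
    const double sr6 = sr2 * sr2 * sr2;
    const double sr12 = sr6 * sr6;
    double coef = 24.0 * p.eps * (2.0 * sr12 - sr6) * sr2 * p.inv_s2;
    if (r2 <= p.rmin2) {
      if (want_energy)
        e_ah += 4.0 * p.eps * (sr12 - sr6) + (1.0 - p.lam) * p.eps;
    } else {
      coef *= p.lam;
      if (want_energy) e_ah += p.lam * 4.0 * p.eps * (sr12 - sr6);
    }
    F[3 * i] += coef * dx; F[3 * i + 1] += coef * dy; F[3 * i + 2] += coef * dz;
    F[3 * j] -= coef * dx; F[3 * j + 1] -= coef * dy; F[3 * j + 2] -= coef * dz;
  }
}

static void nb_forces_charged(const Sys& S, const double* X,
                              const std::vector<PairEntry>& plist,
                              double* F, double& e_ah, double& e_dh,
                              bool want_energy) {
  const double L = S.box, halfL = 0.5 * S.box;
  const double dhcut2 = S.dhcut * S.dhcut;
  for (const PairEntry& p : plist) {
    const int i = p.i, j = p.j;
    double dx = X[3 * i] - X[3 * j];
    double dy = X[3 * i + 1] - X[3 * j + 1];
    double dz = X[3 * i + 2] - X[3 * j + 2];
    if (L > 0) {
      if (dx > halfL) dx -= L; else if (dx < -halfL) dx += L;
      if (dy > halfL) dy -= L; else if (dy < -halfL) dy += L;
      if (dz > halfL) dz -= L; else if (dz < -halfL) dz += L;
    }
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < 1e-8) r2 = 1e-8; // coincident beads: keep forces finite
    double coef = 0.0;
    if (r2 < p.ahcut2) {
      const double sr2 = p.s2 / r2;
      const double sr6 = sr2 * sr2 * sr2;
      const double sr12 = sr6 * sr6;
      const double c = 24.0 * p.eps * (2.0 * sr12 - sr6) * sr2 * p.inv_s2;
      if (r2 <= p.rmin2) {
        coef = c;
        if (want_energy)
          e_ah += 4.0 * p.eps * (sr12 - sr6) + (1.0 - p.lam) * p.eps;
      } else {
        coef = p.lam * c;
        if (want_energy) e_ah += p.lam * 4.0 * p.eps * (sr12 - sr6);
      }
    }
    if (p.qq != 0.0 && r2 < dhcut2) {
      const double r = std::sqrt(r2);
      const double sc = S.ke_coul * p.qq * exp_neg(-r * S.kappa) / r;
      if (want_energy) e_dh += sc;
      coef += sc * (1.0 / r2 + S.kappa / r);
    }
    if (coef != 0.0) {
      F[3 * i] += coef * dx; F[3 * i + 1] += coef * dy; F[3 * i + 2] += coef * dz;
      F[3 * j] -= coef * dx; F[3 * j + 1] -= coef * dy; F[3 * j + 2] -= coef * dz;
    }
  }
}

static void build_pairs(const Sys& S, const double* X, double skin,
                        std::vector<PairEntry>& pu,
                        std::vector<PairEntry>& pq) {
  pu.clear();
  pq.clear();
  // squared list radii per type pair: AH range, extended to the DH
  // cutoff only for charged pairs
  const int nt = S.nt;
  std::vector<double> rl2_0(nt * nt), rl2_q(nt * nt);
  double rlq = S.dhcut + skin;
  for (int a = 0; a < nt; ++a)
    for (int b = 0; b < nt; ++b) {
      double rl = 3.0 * std::sqrt(S.SIG2(a, b)) + skin;
      rl2_0[a + nt * b] = rl * rl;
      double rq = std::max(rl, rlq);
      rl2_q[a + nt * b] = rq * rq;
    }
  for (int i = 0; i < S.n; ++i)
    for (int j = i + 1; j < S.n; ++j) {
      if (S.excluded(i, j)) continue;
      double dx = X[3 * i] - X[3 * j];
      double dy = X[3 * i + 1] - X[3 * j + 1];
      double dz = X[3 * i + 2] - X[3 * j + 2];
      minimg(dx, dy, dz, S.box);
      int ti = S.type[i], tj = S.type[j];
      double qq = S.q[i] * S.q[j];
      double rl2 = qq != 0.0 ? rl2_q[ti + nt * tj] : rl2_0[ti + nt * tj];
      if (dx * dx + dy * dy + dz * dz >= rl2) continue;
      PairEntry p;
      p.i = i; p.j = j;
      p.s2 = S.SIG2(ti, tj);
      p.inv_s2 = 1.0 / p.s2;
      p.rmin2 = CBRT2 * p.s2;
      p.lam = S.LAM(ti, tj);
      p.eps = S.EPS(ti, tj) * S.sasa[i] * S.sasa[j];
      p.qq = qq;
      p.ahcut2 = 9.0 * p.s2;
      if (qq != 0.0) pq.push_back(p); else pu.push_back(p);
    }
}

// [[Rcpp::export]]
List cpp_forces_energy(NumericMatrix coords, List sys,
                       double bondKScale = 1.0) {
  Sys S = unpack(sys);
  if (coords.nrow() != S.n) stop("coordinate/bead count mismatch");
  std::vector<double> X(3 * S.n), F(3 * S.n, 0.0);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) X[3 * i + d] = coords(i, d);
  double eb = 0, ea = 0, ed = 0;
  bond_forces(S, X.data(), F.data(), eb, true, bondKScale);
  nb_forces_full(S, X.data(), F.data(), ea, ed, true);
  NumericMatrix Fm(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) Fm(i, d) = F[3 * i + d];
  for (int i = 0; i < 3 * S.n; ++i)
    if (!std::isfinite(F[i])) stop("non-finite force encountered");
  return List::create(_["forces"] = Fm, _["e_bond"] = eb,
                      _["e_ah"] = ea, _["e_dh"] = ed,
                      _["e_total"] = eb + ea + ed);
}

// ---------------------------------------------------------------------------
// Rigid-body bookkeeping

struct RigidBody {
  std::vector<int> ids;       // 0-based member bead ids
  double M;
  double com[3], V[3];
  double quat[4];             // principal-body -> lab
  double omega[3];            // body frame (principal axes), rad/fs
  double I[3];                // principal moments, g/mol A^2
  std::vector<double> body;   // principal-frame member coords (3 per bead)
};

static void quat_to_mat(const double q[4], double R[9]) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0] = 1 - 2 * (y * y + z * z); R[1] = 2 * (x * y - w * z); R[2] = 2 * (x * z + w * y);
  R[3] = 2 * (x * y + w * z); R[4] = 1 - 2 * (x * x + z * z); R[5] = 2 * (y * z - w * x);
  R[6] = 2 * (x * z - w * y); R[7] = 2 * (y * z + w * x); R[8] = 1 - 2 * (x * x + y * y);
}

static void quat_mult(const double a[4], const double b[4], double out[4]) {
  out[0] = a[0] * b[0] - a[1] * b[1] - a[2] * b[2] - a[3] * b[3];
  out[1] = a[0] * b[1] + a[1] * b[0] + a[2] * b[3] - a[3] * b[2];
  out[2] = a[0] * b[2] - a[1] * b[3] + a[2] * b[0] + a[3] * b[1];
  out[3] = a[0] * b[3] + a[1] * b[2] - a[2] * b[1] + a[3] * b[0];
}

static void quat_normalize(double q[4]) {
  double s = std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2] + q[3] * q[3]);
  for (int k = 0; k < 4; ++k) q[k] /= s;
}

// rotate quaternion by body-frame angular velocity over time h
static void quat_advance(double q[4], const double w[3], double h) {
  double wn = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  if (wn < 1e-300) return;
  double th = 0.5 * wn * h;
  double s = std::sin(th) / wn;
  double dq[4] = {std::cos(th), s * w[0], s * w[1], s * w[2]};
  double out[4];
  quat_mult(q, dq, out); // body-frame convention
  for (int k = 0; k < 4; ++k) q[k] = out[k];
  quat_normalize(q);
}

// 3x3 symmetric eigen-decomposition (Jacobi); A row-major, V columns = vectors
static void jacobi3(double A[9], double eval[3], double V[9]) {
  double B[9];
  for (int k = 0; k < 9; ++k) { B[k] = A[k]; V[k] = 0.0; }
  V[0] = V[4] = V[8] = 1.0;
  for (int sweep = 0; sweep < 64; ++sweep) {
    double off = std::fabs(B[1]) + std::fabs(B[2]) + std::fabs(B[5]);
    if (off < 1e-14) break;
    int pairs[3][2] = {{0, 1}, {0, 2}, {1, 2}};
    for (int pp = 0; pp < 3; ++pp) {
      int p = pairs[pp][0], qi = pairs[pp][1];
      double apq = B[3 * p + qi];
      if (std::fabs(apq) < 1e-300) continue;
      double app = B[3 * p + p], aqq = B[3 * qi + qi];
      double phi = 0.5 * std::atan2(2 * apq, aqq - app);
      double c = std::cos(phi), s = std::sin(phi);
      for (int k = 0; k < 3; ++k) {
        double bkp = B[3 * k + p], bkq = B[3 * k + qi];
        B[3 * k + p] = c * bkp - s * bkq;
        B[3 * k + qi] = s * bkp + c * bkq;
      }
      for (int k = 0; k < 3; ++k) {
        double bpk = B[3 * p + k], bqk = B[3 * qi + k];
        B[3 * p + k] = c * bpk - s * bqk;
        B[3 * qi + k] = s * bpk + c * bqk;
      }
      for (int k = 0; k < 3; ++k) {
        double vkp = V[3 * k + p], vkq = V[3 * k + qi];
        V[3 * k + p] = c * vkp - s * vkq;
        V[3 * k + qi] = s * vkp + c * vkq;
      }
    }
  }
  for (int k = 0; k < 3; ++k) eval[k] = B[3 * k + k];
}

static void mat_to_quat(const double R[9], double q[4]) {
  double tr = R[0] + R[4] + R[8];
  if (tr > 0) {
    double s = std::sqrt(tr + 1.0) * 2;
    q[0] = 0.25 * s;
    q[1] = (R[7] - R[5]) / s;
    q[2] = (R[2] - R[6]) / s;
    q[3] = (R[3] - R[1]) / s;
  } else if (R[0] > R[4] && R[0] > R[8]) {
    double s = std::sqrt(1.0 + R[0] - R[4] - R[8]) * 2;
    q[0] = (R[7] - R[5]) / s; q[1] = 0.25 * s;
    q[2] = (R[1] + R[3]) / s; q[3] = (R[2] + R[6]) / s;
  } else if (R[4] > R[8]) {
    double s = std::sqrt(1.0 + R[4] - R[0] - R[8]) * 2;
    q[0] = (R[2] - R[6]) / s; q[1] = (R[1] + R[3]) / s;
    q[2] = 0.25 * s; q[3] = (R[5] + R[7]) / s;
  } else {
    double s = std::sqrt(1.0 + R[8] - R[0] - R[4]) * 2;
    q[0] = (R[3] - R[1]) / s; q[1] = (R[2] + R[6]) / s;
    q[2] = (R[5] + R[7]) / s; q[3] = 0.25 * s;
  }
  quat_normalize(q);
}

static std::vector<RigidBody> setup_rigid(const Sys& S, const double* X) {
  int ng = 0;
  for (int i = 0; i < S.n; ++i) ng = std::max(ng, S.rigid[i]);
  std::vector<RigidBody> bodies(ng);
  for (int i = 0; i < S.n; ++i)
    if (S.rigid[i] > 0) bodies[S.rigid[i] - 1].ids.push_back(i);
  for (auto& b : bodies) {
    if (b.ids.size() < 3) stop("rigid group needs >= 3 beads");
    b.M = 0;
    b.com[0] = b.com[1] = b.com[2] = 0;
    for (int i : b.ids) {
      b.M += S.mass[i];
      for (int d = 0; d < 3; ++d) b.com[d] += S.mass[i] * X[3 * i + d];
    }
    for (int d = 0; d < 3; ++d) b.com[d] /= b.M;
    double I[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
    for (int i : b.ids) {
      double r[3];
      for (int d = 0; d < 3; ++d) r[d] = X[3 * i + d] - b.com[d];
      double m = S.mass[i];
      double rr = r[0] * r[0] + r[1] * r[1] + r[2] * r[2];
      for (int a = 0; a < 3; ++a)
        for (int c = 0; c < 3; ++c)
          I[3 * a + c] += m * ((a == c ? rr : 0.0) - r[a] * r[c]);
    }
    double eval[3], P[9];
    jacobi3(I, eval, P);
    double emax = std::max({eval[0], eval[1], eval[2]});
    double emin = std::min({eval[0], eval[1], eval[2]});
    if (emin <= 1e-9 * emax)
      stop("degenerate inertia tensor: rigid group is (near-)collinear");
    // ensure right-handed frame
    double det = P[0] * (P[4] * P[8] - P[5] * P[7])
               - P[1] * (P[3] * P[8] - P[5] * P[6])
               + P[2] * (P[3] * P[7] - P[4] * P[6]);
    if (det < 0) { P[2] = -P[2]; P[5] = -P[5]; P[8] = -P[8]; }
    for (int k = 0; k < 3; ++k) b.I[k] = eval[k];
    mat_to_quat(P, b.quat);
    b.body.resize(3 * b.ids.size());
    for (size_t k = 0; k < b.ids.size(); ++k) {
      int i = b.ids[k];
      double r[3];
      for (int d = 0; d < 3; ++d) r[d] = X[3 * i + d] - b.com[d];
      // principal-frame coords: P^T r  (columns of P are principal axes)
      for (int a = 0; a < 3; ++a)
        b.body[3 * k + a] = P[0 + a] * r[0] + P[3 + a] * r[1] + P[6 + a] * r[2];
    }
    for (int d = 0; d < 3; ++d) { b.V[d] = 0; b.omega[d] = 0; }
  }
  return bodies;
}

static void rigid_project(const std::vector<RigidBody>& bodies, double* X) {
  for (const auto& b : bodies) {
    double R[9];
    quat_to_mat(b.quat, R);
    for (size_t k = 0; k < b.ids.size(); ++k) {
      int i = b.ids[k];
      const double* c = &b.body[3 * k];
      X[3 * i]     = b.com[0] + R[0] * c[0] + R[1] * c[1] + R[2] * c[2];
      X[3 * i + 1] = b.com[1] + R[3] * c[0] + R[4] * c[1] + R[5] * c[2];
      X[3 * i + 2] = b.com[2] + R[6] * c[0] + R[7] * c[1] + R[8] * c[2];
    }
  }
}

// ---------------------------------------------------------------------------
// Molecular dynamics run: BAOAB Langevin (gamma=0 -> velocity Verlet NVE)

// [[Rcpp::export]]
List cpp_run(NumericMatrix coords, List sys, int nsteps, double dt,
             double gamma_ps, double temperature, int out_stride,
             int nl_every, double skin, int seed, double cap,
             Nullable<NumericMatrix> ext_force = R_NilValue,
             Nullable<NumericMatrix> vel0 = R_NilValue,
             double bondKScale = 1.0) {
  Sys S = unpack(sys);
  int n = S.n;
  if (coords.nrow() != n) stop("coordinate/bead count mismatch");
  std::vector<double> X(3 * n), Vv(3 * n, 0.0), F(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) X[3 * i + d] = coords(i, d);

  std::vector<double> Fext(3 * n, 0.0);
  if (ext_force.isNotNull()) {
    NumericMatrix E(ext_force);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) Fext[3 * i + d] = E(i, d);
  }

  std::vector<RigidBody> bodies = setup_rigid(S, X.data());
  std::vector<bool> isflex(n, true);
  for (auto& b : bodies) for (int i : b.ids) isflex[i] = false;
  int nflex = 0;
  for (int i = 0; i < n; ++i) if (isflex[i]) ++nflex;
  int dof = 3 * nflex + 6 * (int)bodies.size();

  Rng rng((uint64_t)seed * 2654435761ULL + 1442695040888963407ULL);
  double gamma = gamma_ps * 1e-3; // fs^-1
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt((1.0 - c1 * c1) * KB * temperature * FTM2V);

  // velocities
  if (vel0.isNotNull()) {
    NumericMatrix V0(vel0);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) Vv[3 * i + d] = V0(i, d);
  } else if (temperature > 0) {
    for (int i = 0; i < n; ++i)
      if (isflex[i]) {
        double sv = std::sqrt(KB * temperature * FTM2V / S.mass[i]);
        for (int d = 0; d < 3; ++d) Vv[3 * i + d] = sv * rng.norm();
      }
    for (auto& b : bodies) {
      double sv = std::sqrt(KB * temperature * FTM2V / b.M);
      for (int d = 0; d < 3; ++d) b.V[d] = sv * rng.norm();
      for (int k = 0; k < 3; ++k)
        b.omega[k] = std::sqrt(KB * temperature * FTM2V / b.I[k]) * rng.norm();
    }
  }

  std::vector<PairEntry> plist_u, plist_q;
  std::vector<double> Xbuild(3 * n);
  build_pairs(S, X.data(), skin, plist_u, plist_q);
  Xbuild = X;

  auto forces = [&](bool want_e, double* eb, double* ea, double* ed) {
    std::fill(F.begin(), F.end(), 0.0);
    double b = 0, a = 0, d = 0;
    bond_forces(S, X.data(), F.data(), b, want_e, bondKScale);
    nb_forces_uncharged(S, X.data(), plist_u, F.data(), a, want_e);
    nb_forces_charged(S, X.data(), plist_q, F.data(), a, d, want_e);
    for (int i = 0; i < 3 * n; ++i) F[i] += Fext[i];
    if (eb) { *eb = b; *ea = a; *ed = d; }
  };

  int nframes = nsteps / out_stride + 1;
  NumericVector arr(Dimension(n, 3, nframes));
  NumericVector f_eb(nframes), f_ea(nframes), f_ed(nframes),
      f_ke(nframes), f_T(nframes), f_step(nframes);

  auto kinetic = [&]() {
    double ke = 0;
    for (int i = 0; i < n; ++i)
      if (isflex[i])
        ke += 0.5 * S.mass[i] *
              (Vv[3 * i] * Vv[3 * i] + Vv[3 * i + 1] * Vv[3 * i + 1] +
               Vv[3 * i + 2] * Vv[3 * i + 2]);
    for (auto& b : bodies) {
      ke += 0.5 * b.M * (b.V[0] * b.V[0] + b.V[1] * b.V[1] + b.V[2] * b.V[2]);
      for (int k = 0; k < 3; ++k) ke += 0.5 * b.I[k] * b.omega[k] * b.omega[k];
    }
    return ke / FTM2V; // kcal/mol
  };

  auto record = [&](int fidx, int step) {
    double eb, ea, ed;
    forces(true, &eb, &ea, &ed);
    double ke = kinetic();
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        arr[fidx * 3 * n + d * n + i] = X[3 * i + d];
    f_eb[fidx] = eb; f_ea[fidx] = ea; f_ed[fidx] = ed;
    f_ke[fidx] = ke;
    f_T[fidx] = dof > 0 ? 2.0 * ke / (dof * KB) : 0.0;
    f_step[fidx] = step;
  };

  forces(false, nullptr, nullptr, nullptr);
  record(0, 0);
  int fidx = 1;
  bool blowup = false;
  int blowstep = -1;
  std::vector<double> Xprev(3 * n);

  // bound rigid-body motion when displacement capping is active, so one
  // overloaded kick cannot translate or spin a group arbitrarily far
  auto clamp_bodies = [&]() {
    if (cap <= 0) return;
    double vmax = cap / dt;
    for (auto& b : bodies) {
      double v2 = b.V[0] * b.V[0] + b.V[1] * b.V[1] + b.V[2] * b.V[2];
      if (v2 > vmax * vmax) {
        double s = vmax / std::sqrt(v2);
        for (int d = 0; d < 3; ++d) b.V[d] *= s;
      }
      double rmax = 1e-6;
      for (size_t k = 0; k < b.body.size(); k += 3) {
        double r2 = b.body[k] * b.body[k] + b.body[k + 1] * b.body[k + 1] +
                    b.body[k + 2] * b.body[k + 2];
        rmax = std::max(rmax, std::sqrt(r2));
      }
      double wmax = vmax / rmax;
      double w2 = b.omega[0] * b.omega[0] + b.omega[1] * b.omega[1] +
                  b.omega[2] * b.omega[2];
      if (w2 > wmax * wmax) {
        double s = wmax / std::sqrt(w2);
        for (int d = 0; d < 3; ++d) b.omega[d] *= s;
      }
    }
  };

  for (int step = 1; step <= nsteps; ++step) {
    Xprev = X;
    // B: half kick
    for (int i = 0; i < n; ++i)
      if (isflex[i]) {
        double a = 0.5 * dt * FTM2V / S.mass[i];
        for (int d = 0; d < 3; ++d) Vv[3 * i + d] += a * F[3 * i + d];
      }
    for (auto& b : bodies) {
      double Fg[3] = {0, 0, 0}, tau[3] = {0, 0, 0};
      double R[9];
      quat_to_mat(b.quat, R);
      for (size_t k = 0; k < b.ids.size(); ++k) {
        int i = b.ids[k];
        for (int d = 0; d < 3; ++d) Fg[d] += F[3 * i + d];
        double rx = X[3 * i] - b.com[0], ry = X[3 * i + 1] - b.com[1],
               rz = X[3 * i + 2] - b.com[2];
        tau[0] += ry * F[3 * i + 2] - rz * F[3 * i + 1];
        tau[1] += rz * F[3 * i] - rx * F[3 * i + 2];
        tau[2] += rx * F[3 * i + 1] - ry * F[3 * i];
      }
      // torque to principal body frame: R^T tau
      double tb[3];
      tb[0] = R[0] * tau[0] + R[3] * tau[1] + R[6] * tau[2];
      tb[1] = R[1] * tau[0] + R[4] * tau[1] + R[7] * tau[2];
      tb[2] = R[2] * tau[0] + R[5] * tau[1] + R[8] * tau[2];
      for (int d = 0; d < 3; ++d) b.V[d] += 0.5 * dt * FTM2V * Fg[d] / b.M;
      // Euler equations with gyroscopic term
      double w0 = b.omega[0], w1 = b.omega[1], w2 = b.omega[2];
      double g0 = (b.I[1] - b.I[2]) * w1 * w2;
      double g1 = (b.I[2] - b.I[0]) * w2 * w0;
      double g2 = (b.I[0] - b.I[1]) * w0 * w1;
      b.omega[0] += 0.5 * dt * (FTM2V * tb[0] + g0) / b.I[0];
      b.omega[1] += 0.5 * dt * (FTM2V * tb[1] + g1) / b.I[1];
      b.omega[2] += 0.5 * dt * (FTM2V * tb[2] + g2) / b.I[2];
    }
    clamp_bodies();
    // A: half drift
    for (int i = 0; i < n; ++i)
      if (isflex[i])
        for (int d = 0; d < 3; ++d) X[3 * i + d] += 0.5 * dt * Vv[3 * i + d];
    for (auto& b : bodies) {
      for (int d = 0; d < 3; ++d) b.com[d] += 0.5 * dt * b.V[d];
      quat_advance(b.quat, b.omega, 0.5 * dt);
    }
    // O: thermostat
    if (gamma > 0 && temperature >= 0) {
      for (int i = 0; i < n; ++i)
        if (isflex[i]) {
          double sv = c2 / std::sqrt(S.mass[i]);
          for (int d = 0; d < 3; ++d)
            Vv[3 * i + d] = c1 * Vv[3 * i + d] + sv * rng.norm();
        }
      for (auto& b : bodies) {
        double sv = c2 / std::sqrt(b.M);
        for (int d = 0; d < 3; ++d) b.V[d] = c1 * b.V[d] + sv * rng.norm();
        for (int k = 0; k < 3; ++k)
          b.omega[k] = c1 * b.omega[k] + c2 / std::sqrt(b.I[k]) * rng.norm();
      }
    }
    // A: half drift
    for (int i = 0; i < n; ++i)
      if (isflex[i])
        for (int d = 0; d < 3; ++d) X[3 * i + d] += 0.5 * dt * Vv[3 * i + d];
    for (auto& b : bodies) {
      for (int d = 0; d < 3; ++d) b.com[d] += 0.5 * dt * b.V[d];
      quat_advance(b.quat, b.omega, 0.5 * dt);
    }
    rigid_project(bodies, X.data());

    // displacement cap / blow-up detection
    double maxdisp2 = 0;
    for (int i = 0; i < n; ++i) {
      double dx = X[3 * i] - Xprev[3 * i];
      double dy = X[3 * i + 1] - Xprev[3 * i + 1];
      double dz = X[3 * i + 2] - Xprev[3 * i + 2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (cap > 0 && d2 > cap * cap && isflex[i]) {
        double sc = cap / std::sqrt(d2);
        X[3 * i] = Xprev[3 * i] + dx * sc;
        X[3 * i + 1] = Xprev[3 * i + 1] + dy * sc;
        X[3 * i + 2] = Xprev[3 * i + 2] + dz * sc;
        // clamp speed to cap/dt so repeated kicks cannot accumulate
        double v2 = Vv[3 * i] * Vv[3 * i] + Vv[3 * i + 1] * Vv[3 * i + 1] +
                    Vv[3 * i + 2] * Vv[3 * i + 2];
        double vmax = cap / dt;
        if (v2 > vmax * vmax) {
          double vs = vmax / std::sqrt(v2);
          for (int d = 0; d < 3; ++d) Vv[3 * i + d] *= vs;
        }
        d2 = cap * cap;
      }
      maxdisp2 = std::max(maxdisp2, d2);
    }
    if (cap <= 0 && maxdisp2 > 100.0) { blowup = true; blowstep = step; }

    forces(false, nullptr, nullptr, nullptr);
    // B: half kick (same structure as above)
    for (int i = 0; i < n; ++i)
      if (isflex[i]) {
        double a = 0.5 * dt * FTM2V / S.mass[i];
        for (int d = 0; d < 3; ++d) Vv[3 * i + d] += a * F[3 * i + d];
      }
    for (auto& b : bodies) {
      double Fg[3] = {0, 0, 0}, tau[3] = {0, 0, 0};
      double R[9];
      quat_to_mat(b.quat, R);
      for (size_t k = 0; k < b.ids.size(); ++k) {
        int i = b.ids[k];
        for (int d = 0; d < 3; ++d) Fg[d] += F[3 * i + d];
        double rx = X[3 * i] - b.com[0], ry = X[3 * i + 1] - b.com[1],
               rz = X[3 * i + 2] - b.com[2];
        tau[0] += ry * F[3 * i + 2] - rz * F[3 * i + 1];
        tau[1] += rz * F[3 * i] - rx * F[3 * i + 2];
        tau[2] += rx * F[3 * i + 1] - ry * F[3 * i];
      }
      double tb[3];
      tb[0] = R[0] * tau[0] + R[3] * tau[1] + R[6] * tau[2];
      tb[1] = R[1] * tau[0] + R[4] * tau[1] + R[7] * tau[2];
      tb[2] = R[2] * tau[0] + R[5] * tau[1] + R[8] * tau[2];
      for (int d = 0; d < 3; ++d) b.V[d] += 0.5 * dt * FTM2V * Fg[d] / b.M;
      double w0 = b.omega[0], w1 = b.omega[1], w2 = b.omega[2];
      double g0 = (b.I[1] - b.I[2]) * w1 * w2;
      double g1 = (b.I[2] - b.I[0]) * w2 * w0;
      double g2 = (b.I[0] - b.I[1]) * w0 * w1;
      b.omega[0] += 0.5 * dt * (FTM2V * tb[0] + g0) / b.I[0];
      b.omega[1] += 0.5 * dt * (FTM2V * tb[1] + g1) / b.I[1];
      b.omega[2] += 0.5 * dt * (FTM2V * tb[2] + g2) / b.I[2];
    }
    clamp_bodies();

    if (blowup) break;

    // neighbor list maintenance
    bool rebuild = (step % nl_every == 0);
    if (!rebuild) {
      double half = 0.5 * skin, h2 = half * half;
      for (int i = 0; i < n && !rebuild; ++i) {
        double dx = X[3 * i] - Xbuild[3 * i];
        double dy = X[3 * i + 1] - Xbuild[3 * i + 1];
        double dz = X[3 * i + 2] - Xbuild[3 * i + 2];
        if (dx * dx + dy * dy + dz * dz > h2) rebuild = true;
      }
    }
    if (rebuild) {
      build_pairs(S, X.data(), skin, plist_u, plist_q);
      Xbuild = X;
      forces(false, nullptr, nullptr, nullptr);
    }

    if (step % out_stride == 0 && fidx < nframes) {
      record(fidx, step);
      ++fidx;
    }
  }

  NumericMatrix Xout(n, 3), Vout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      Xout(i, d) = X[3 * i + d];
      Vout(i, d) = Vv[3 * i + d];
    }
  return List::create(
      _["coords"] = arr, _["steps"] = f_step, _["e_bond"] = f_eb,
      _["e_ah"] = f_ea, _["e_dh"] = f_ed, _["kinetic"] = f_ke,
      _["temperature"] = f_T, _["final_coords"] = Xout,
      _["final_vel"] = Vout, _["n_frames"] = fidx,
      _["blowup"] = blowup, _["blowup_step"] = blowstep, _["dof"] = dof);
}

// ---------------------------------------------------------------------------
// FIRE minimization (flexible beads; rigid groups held fixed)

// [[Rcpp::export]]
List cpp_minimize(NumericMatrix coords, List sys, double ftol,
                  int maxiter, double bondKScale = 1.0) {
  Sys S = unpack(sys);
  int n = S.n;
  std::vector<double> X(3 * n), V(3 * n, 0.0), F(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) X[3 * i + d] = coords(i, d);
  std::vector<bool> mobile(n, true);
  for (int i = 0; i < n; ++i) if (S.rigid[i] != 0) mobile[i] = false;

  double dt = 0.5, dtmax = 5.0;
  double alpha = 0.1;
  int npos = 0;
  double eprev = R_PosInf;
  double fmax = R_PosInf;
  int it = 0;
  bool converged = false;

  auto eval = [&]() {
    std::fill(F.begin(), F.end(), 0.0);
    double eb = 0, ea = 0, ed = 0;
    bond_forces(S, X.data(), F.data(), eb, true, bondKScale);
    nb_forces_full(S, X.data(), F.data(), ea, ed, true);
    return eb + ea + ed;
  };

  double e = eval();
  for (it = 0; it < maxiter; ++it) {
    fmax = 0;
    double P = 0, vnorm = 0, fnorm = 0;
    for (int i = 0; i < n; ++i)
      if (mobile[i])
        for (int d = 0; d < 3; ++d) {
          double f = F[3 * i + d];
          fmax = std::max(fmax, std::fabs(f));
          P += f * V[3 * i + d];
          vnorm += V[3 * i + d] * V[3 * i + d];
          fnorm += f * f;
        }
    if (fmax < ftol) { converged = true; break; }
    vnorm = std::sqrt(vnorm); fnorm = std::sqrt(fnorm);
    if (P > 0) {
      ++npos;
      if (npos > 5) { dt = std::min(dt * 1.1, dtmax); alpha *= 0.99; }
      if (fnorm > 0)
        for (int i = 0; i < n; ++i)
          if (mobile[i])
            for (int d = 0; d < 3; ++d)
              V[3 * i + d] = (1 - alpha) * V[3 * i + d] +
                             alpha * vnorm * F[3 * i + d] / fnorm;
    } else {
      npos = 0; dt *= 0.5; alpha = 0.1;
      std::fill(V.begin(), V.end(), 0.0);
    }
    for (int i = 0; i < n; ++i)
      if (mobile[i])
        for (int d = 0; d < 3; ++d) {
          V[3 * i + d] += dt * F[3 * i + d]; // unit-mass descent dynamics
          double dx = dt * V[3 * i + d];
          if (dx > 0.2) dx = 0.2;
          if (dx < -0.2) dx = -0.2;
          X[3 * i + d] += dx;
        }
    double enew = eval();
    if (enew > e + 1e-12 && P <= 0) { /* keep shrinking dt on next loop */ }
    eprev = e;
    e = enew;
    (void)eprev;
  }
  NumericMatrix Xout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) Xout(i, d) = X[3 * i + d];
  return List::create(_["coords"] = Xout, _["converged"] = converged,
                      _["fmax"] = fmax, _["iterations"] = it,
                      _["energy"] = e);
}
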