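// Core simulation engine: neighbor-listed nonbonded forces (LJ 12-6,
// screened Coulomb), harmonic bonds/angles, 9-3 surface wall, one-sided
// center-of-mass z-restraint, constant COM pulling force, an external 1D
// double-well (toy systems), leapfrog Langevin integration with frozen
// beads, and metadynamics (standard / well-tempered) on COM or contacts
// collective variables with grid-backed bias storage.
//
// Units package-wide: nm, ps, amu, kJ/mol, e, K.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static const double KB = 0.0083144621;   // kJ mol-1 K-1
static const double FCOUL = 138.935458;  // kJ mol-1 nm e-2

// ---------------------------------------------------------------------------
// geometry helpers

struct BoxDef {
  double L[3];
  bool per[3];
};

static inline void min_image(double* d, const BoxDef& box) {
  for (int k = 0; k < 3; ++k) {
    if (box.per[k] && box.L[k] > 0) {
      d[k] -= box.L[k] * std::round(d[k] / box.L[k]);
    }
  }
}

// ---------------------------------------------------------------------------
// force field definition

struct FFDef {
  int ntype;
  std::vector<double> sigma;  // ntype*ntype
  std::vector<double> eps;
  double rc;
  double eps_r;
  bool lj_shift;     // cut-and-shift LJ at rc
  bool coul_shift;   // energy-shift Coulomb at rc
  // 9-3 wall (acts on all mobile beads, z measured from zref)
  bool has_wall;
  double wall_eps, wall_sigma, wall_zref;
  // one-sided COM z restraint
  bool has_restraint;
  double res_z0, res_kappa;
  int res_exp;
  std::vector<int> res_group;  // 0-based bead indices
  // constant COM force
  bool has_pull;
  double pull_f[3];
  std::vector<int> pull_group;
  double pull_mass;  // total mass of pull group
  // external 1D double-well along x: U = h*((x/a)^2 - 1)^2, mobile beads
  bool has_dwell;
  double dw_h, dw_a;
};

struct Topology {
  // bonds: i, j (0-based), r0, k
  std::vector<int> b_i, b_j;
  std::vector<double> b_r0, b_k;
  // angles: i-j-k, theta0 (rad), k (kJ/mol/rad^2)
  std::vector<int> a_i, a_j, a_k;
  std::vector<double> a_t0, a_kt;
  std::unordered_set<int64_t> excl;  // i*N+j with i<j
};

static inline int64_t pair_key(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (int64_t)i * n + j;
}

struct EnergyAcc {
  double lj = 0, coul = 0, wall = 0, bonded = 0, restraint = 0, external = 0;
  double total() const { return lj + coul + wall + bonded + restraint + external; }
};

// ---------------------------------------------------------------------------
// neighbor list (Verlet, O(N^2) build; frozen-frozen pairs skipped)

struct NeighborList {
  std::vector<int> pi, pj;
  std::vector<double> ref_pos;  // positions at build time
  double skin = 0.4;
  bool use_list = true;

  void build(const std::vector<double>& pos, int n, const BoxDef& box,
             const std::vector<char>& frozen, const Topology& top, double rc) {
    pi.clear();
    pj.clear();
    double rl = rc + skin;
    double rl2 = rl * rl;
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (frozen[i] && frozen[j]) continue;
        if (top.excl.count(pair_key(i, j, n))) continue;
        double d[3] = {pos[3 * i] - pos[3 * j], pos[3 * i + 1] - pos[3 * j + 1],
                       pos[3 * i + 2] - pos[3 * j + 2]};
        min_image(d, box);
        double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
        if (r2 < rl2) {
          pi.push_back(i);
          pj.push_back(j);
        }
      }
    }
    ref_pos = pos;
  }

  bool stale(const std::vector<double>& pos, int n) const {
    double lim2 = 0.25 * skin * skin;  // (skin/2)^2
    for (int i = 0; i < 3 * n; i += 3) {
      double dx = pos[i] - ref_pos[i];
      double dy = pos[i + 1] - ref_pos[i + 1];
      double dz = pos[i + 2] - ref_pos[i + 2];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }
};

// ---------------------------------------------------------------------------
// pairwise + bonded + wall + restraint + external forces

static void compute_forces(const std::vector<double>& pos,
                           const std::vector<double>& mass,
                           const std::vector<double>& charge,
                           const std::vector<int>& type,
                           const std::vector<char>& frozen, int n,
                           const BoxDef& box, const FFDef& ff,
                           const Topology& top, NeighborList& nl,
                           std::vector<double>& frc, EnergyAcc& en) {
  std::fill(frc.begin(), frc.end(), 0.0);
  en = EnergyAcc();

  double rc2 = ff.rc * ff.rc;
  int nt = ff.ntype;

  auto pair_force = [&](int i, int j) {
    double d[3] = {pos[3 * i] - pos[3 * j], pos[3 * i + 1] - pos[3 * j + 1],
                   pos[3 * i + 2] - pos[3 * j + 2]};
    min_image(d, box);
    double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    if (r2 >= rc2 || r2 <= 0) return;
    double r = std::sqrt(r2);
    int ti = type[i], tj = type[j];
    double sg = ff.sigma[ti * nt + tj];
    double ep = ff.eps[ti * nt + tj];
    double fr = 0.0;  // dU/dr * (-1/r) accumulated as f_scalar/r
    if (ep > 0 && sg > 0) {
      double sr2 = sg * sg / r2;
      double sr6 = sr2 * sr2 * sr2;
      double sr12 = sr6 * sr6;
      double u = 4.0 * ep * (sr12 - sr6);
      if (ff.lj_shift) {
        double src2 = sg * sg / rc2;
        double src6 = src2 * src2 * src2;
        u -= 4.0 * ep * (src6 * src6 - src6);
      }
      en.lj += u;
      fr += 24.0 * ep * (2.0 * sr12 - sr6) / r2;
    }
    double qq = charge[i] * charge[j];
    if (qq != 0.0) {
      double pref = FCOUL * qq / ff.eps_r;
      double u = pref / r;
      if (ff.coul_shift) u -= pref / ff.rc;
      en.coul += u;
      fr += pref / (r2 * r);
    }
    if (fr != 0.0) {
      for (int k = 0; k < 3; ++k) {
        double f = fr * d[k];
        frc[3 * i + k] += f;
        frc[3 * j + k] -= f;
      }
    }
  };

  if (nl.use_list) {
    size_t np = nl.pi.size();
    for (size_t p = 0; p < np; ++p) pair_force(nl.pi[p], nl.pj[p]);
  } else {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (frozen[i] && frozen[j]) continue;
        if (top.excl.count(pair_key(i, j, n))) continue;
        pair_force(i, j);
      }
  }

  // bonds
  for (size_t b = 0; b < top.b_i.size(); ++b) {
    int i = top.b_i[b], j = top.b_j[b];
    double d[3] = {pos[3 * i] - pos[3 * j], pos[3 * i + 1] - pos[3 * j + 1],
                   pos[3 * i + 2] - pos[3 * j + 2]};
    min_image(d, box);
    double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (r <= 0) continue;
    double dr = r - top.b_r0[b];
    en.bonded += 0.5 * top.b_k[b] * dr * dr;
    double fr = -top.b_k[b] * dr / r;
    for (int k = 0; k < 3; ++k) {
      double f = fr * d[k];
      frc[3 * i + k] += f;
      frc[3 * j + k] -= f;
    }
  }

  // angles (harmonic in theta)
  for (size_t a = 0; a < top.a_i.size(); ++a) {
    int i = top.a_i[a], j = top.a_j[a], k = top.a_k[a];
    double rij[3], rkj[3];
    for (int c = 0; c < 3; ++c) {
      rij[c] = pos[3 * i + c] - pos[3 * j + c];
      rkj[c] = pos[3 * k + c] - pos[3 * j + c];
    }
    min_image(rij, box);
    min_image(rkj, box);
    double nij = std::sqrt(rij[0] * rij[0] + rij[1] * rij[1] + rij[2] * rij[2]);
    double nkj = std::sqrt(rkj[0] * rkj[0] + rkj[1] * rkj[1] + rkj[2] * rkj[2]);
    if (nij <= 0 || nkj <= 0) continue;
    double cs = (rij[0] * rkj[0] + rij[1] * rkj[1] + rij[2] * rkj[2]) / (nij * nkj);
    cs = std::max(-1.0, std::min(1.0, cs));
    double th = std::acos(cs);
    double dth = th - top.a_t0[a];
    en.bonded += 0.5 * top.a_kt[a] * dth * dth;
    double sn = std::sqrt(std::max(1e-12, 1.0 - cs * cs));
    double coef = top.a_kt[a] * dth / sn;  // -dU/dtheta * (-1/sin) chain
    for (int c = 0; c < 3; ++c) {
      double fi = coef * (rkj[c] / (nij * nkj) - cs * rij[c] / (nij * nij));
      double fk = coef * (rij[c] / (nij * nkj) - cs * rkj[c] / (nkj * nkj));
      frc[3 * i + c] += fi;
      frc[3 * k + c] += fk;
      frc[3 * j + c] -= fi + fk;
    }
  }

  // 9-3 wall on mobile beads: U = eps_w * (3/sqrt(10)) * ((2/15) x^3 - x),
  // x = (sigma_w/dz)^3; well depth = eps_w at dz = sigma_w (2/5)^{1/6}
  if (ff.has_wall) {
    const double C = 3.0 / std::sqrt(10.0);
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      double dz = pos[3 * i + 2] - ff.wall_zref;
      if (dz <= 1e-6) dz = 1e-6;
      double x = ff.wall_sigma / dz;
      double x3 = x * x * x;
      double u = ff.wall_eps * C * ((2.0 / 15.0) * x3 * x3 * x3 - x3);
      en.wall += u;
      // dU/ddz = eps*C*( (2/15)*9 x^9 * (-1/dz) - 3 x^3 * (-1/dz) )
      double dudz = ff.wall_eps * C * (-(6.0 / 5.0) * x3 * x3 * x3 + 3.0 * x3) / dz;
      frc[3 * i + 2] -= dudz;
    }
  }

  // one-sided COM z restraint: U = kappa*(z-z0)^exp for z_com > z0
  if (ff.has_restraint && !ff.res_group.empty()) {
    double M = 0, zc = 0;
    for (int idx : ff.res_group) {
      M += mass[idx];
      zc += mass[idx] * pos[3 * idx + 2];
    }
    zc /= M;
    if (zc > ff.res_z0) {
      double d = zc - ff.res_z0;
      double u = ff.res_kappa * std::pow(d, ff.res_exp);
      en.restraint += u;
      double dudz = ff.res_kappa * ff.res_exp * std::pow(d, ff.res_exp - 1);
      for (int idx : ff.res_group) {
        frc[3 * idx + 2] -= dudz * mass[idx] / M;
      }
    }
  }

  // constant force on group COM, distributed mass-weighted
  if (ff.has_pull && !ff.pull_group.empty()) {
    for (int idx : ff.pull_group) {
      double w = mass[idx] / ff.pull_mass;
      for (int k = 0; k < 3; ++k) frc[3 * idx + k] += ff.pull_f[k] * w;
    }
  }

  // external 1D double-well along x on mobile beads
  if (ff.has_dwell) {
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      double x = pos[3 * i];
      double q = (x / ff.dw_a) * (x / ff.dw_a) - 1.0;
      en.external += ff.dw_h * q * q;
      frc[3 * i] -= 4.0 * ff.dw_h * q * x / (ff.dw_a * ff.dw_a);
    }
  }
}

// ---------------------------------------------------------------------------
// collective variables

struct CVDef {
  int kind = 0;  // 0 none, 1 com_x, 2 com_xy, 3 contacts
  std::vector<int> group;   // COM group or contacts group A
  std::vector<int> groupB;  // contacts group B
  double r0 = 0.6;          // contacts switching radius
  double group_mass = 0;
  int dim() const { return kind == 2 ? 2 : 1; }
};

// COM of a group (positions are integrated unwrapped, so COM is continuous)
static void cv_value(const std::vector<double>& pos, const std::vector<double>& mass,
                     const CVDef& cv, double* s) {
  if (cv.kind == 1 || cv.kind == 2) {
    double cx = 0, cy = 0;
    for (int idx : cv.group) {
      cx += mass[idx] * pos[3 * idx];
      cy += mass[idx] * pos[3 * idx + 1];
    }
    s[0] = cx / cv.group_mass;
    if (cv.kind == 2) s[1] = cy / cv.group_mass;
  } else if (cv.kind == 3) {
    // rational switch sum: w(r) = 1/(1+(r/r0)^6)
    double tot = 0;
    for (int a : cv.group) {
      for (int b : cv.groupB) {
        double d[3] = {pos[3 * a] - pos[3 * b], pos[3 * a + 1] - pos[3 * b + 1],
                       pos[3 * a + 2] - pos[3 * b + 2]};
        double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
        double x6 = std::pow(r2 / (cv.r0 * cv.r0), 3.0);
        tot += 1.0 / (1.0 + x6);
      }
    }
    s[0] = tot;
  }
}

// add bias force -dV/ds * ds/dx to frc
static void cv_apply_bias_force(const std::vector<double>& pos,
                                const std::vector<double>& mass, const CVDef& cv,
                                const double* dVds, std::vector<double>& frc) {
  if (cv.kind == 1 || cv.kind == 2) {
    for (int idx : cv.group) {
      double w = mass[idx] / cv.group_mass;
      frc[3 * idx] -= dVds[0] * w;
      if (cv.kind == 2) frc[3 * idx + 1] -= dVds[1] * w;
    }
  } else if (cv.kind == 3) {
    for (int a : cv.group) {
      for (int b : cv.groupB) {
        double d[3] = {pos[3 * a] - pos[3 * b], pos[3 * a + 1] - pos[3 * b + 1],
                       pos[3 * a + 2] - pos[3 * b + 2]};
        double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
        double r = std::sqrt(r2);
        if (r < 1e-9) continue;
        double x6 = std::pow(r2 / (cv.r0 * cv.r0), 3.0);
        double den = 1.0 + x6;
        // dw/dr = -6 x^6 / (r * den^2)
        double dwdr = -6.0 * x6 / (r * den * den);
        double fr = -dVds[0] * dwdr / r;  // force along d
        for (int k = 0; k < 3; ++k) {
          double f = fr * d[k];
          frc[3 * a + k] += f;
          frc[3 * b + k] -= f;
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// metadynamics bias: grid-backed for COM CVs, kernel-sum for contacts

struct MetaDState {
  int cvdim = 1;
  double height = 0;       // reference kernel height
  double width[2] = {1, 1};
  int stride = 0;
  double bias_factor = 0;  // 0 => standard MetaD
  double temperature = 300;
  bool grid_mode = true;
  // grid
  int nb[2] = {1, 1};
  double lo[2] = {0, 0}, hi[2] = {1, 1}, dx[2] = {1, 1};
  bool per[2] = {false, false};
  std::vector<double> V, G0, G1;  // value and gradient grids
  // kernel bookkeeping (HILLS-like)
  std::vector<double> kc0, kc1, kh, kt;

  void init_grid() {
    if (!grid_mode) return;
    int tot = nb[0] * (cvdim == 2 ? nb[1] : 1);
    V.assign(tot, 0.0);
    G0.assign(tot, 0.0);
    if (cvdim == 2) G1.assign(tot, 0.0);
    for (int d = 0; d < cvdim; ++d) {
      dx[d] = (hi[d] - lo[d]) / (per[d] ? nb[d] : (nb[d] - 1));
    }
  }

  // periodic-aware displacement in CV space
  inline double cvdisp(double s, double c, int d) const {
    double u = s - c;
    if (per[d]) {
      double L = hi[d] - lo[d];
      u -= L * std::round(u / L);
    }
    return u;
  }

  double kernel_sum_value(const double* s, double* grad) const {
    double v = 0;
    if (grad) {
      grad[0] = 0;
      if (cvdim == 2) grad[1] = 0;
    }
    for (size_t i = 0; i < kh.size(); ++i) {
      double u0 = cvdisp(s[0], kc0[i], 0);
      double e = u0 * u0 / (2.0 * width[0] * width[0]);
      double u1 = 0;
      if (cvdim == 2) {
        u1 = cvdisp(s[1], kc1[i], 1);
        e += u1 * u1 / (2.0 * width[1] * width[1]);
      }
      if (e > 25.0) continue;
      double g = kh[i] * std::exp(-e);
      v += g;
      if (grad) {
        grad[0] += -g * u0 / (width[0] * width[0]);
        if (cvdim == 2) grad[1] += -g * u1 / (width[1] * width[1]);
      }
    }
    return v;
  }

  // bilinear interpolation of V (and gradient grids)
  double grid_value(const double* s, double* grad) const {
    double out = 0;
    double gx[2] = {0, 0};
    // locate cell per dim
    double fx[2];
    int i0[2], i1[2];
    for (int d = 0; d < cvdim; ++d) {
      double u = (s[d] - lo[d]) / dx[d];
      if (per[d]) {
        double nbd = nb[d];
        u = u - std::floor(u / nbd) * nbd;
        i0[d] = (int)std::floor(u) % nb[d];
        i1[d] = (i0[d] + 1) % nb[d];
        fx[d] = u - std::floor(u);
      } else {
        if (u <= 0) { i0[d] = i1[d] = 0; fx[d] = 0; }
        else if (u >= nb[d] - 1) { i0[d] = i1[d] = nb[d] - 1; fx[d] = 0; }
        else { i0[d] = (int)std::floor(u); i1[d] = i0[d] + 1; fx[d] = u - i0[d]; }
      }
    }
    if (cvdim == 1) {
      double w0 = 1 - fx[0], w1 = fx[0];
      out = w0 * V[i0[0]] + w1 * V[i1[0]];
      gx[0] = w0 * G0[i0[0]] + w1 * G0[i1[0]];
    } else {
      int n1 = nb[1];
      auto at = [&](const std::vector<double>& A, int a, int b) {
        return A[a * n1 + b];
      };
      double w00 = (1 - fx[0]) * (1 - fx[1]), w01 = (1 - fx[0]) * fx[1];
      double w10 = fx[0] * (1 - fx[1]), w11 = fx[0] * fx[1];
      out = w00 * at(V, i0[0], i0[1]) + w01 * at(V, i0[0], i1[1]) +
            w10 * at(V, i1[0], i0[1]) + w11 * at(V, i1[0], i1[1]);
      gx[0] = w00 * at(G0, i0[0], i0[1]) + w01 * at(G0, i0[0], i1[1]) +
              w10 * at(G0, i1[0], i0[1]) + w11 * at(G0, i1[0], i1[1]);
      gx[1] = w00 * at(G1, i0[0], i0[1]) + w01 * at(G1, i0[0], i1[1]) +
              w10 * at(G1, i1[0], i0[1]) + w11 * at(G1, i1[0], i1[1]);
    }
    if (grad) {
      grad[0] = gx[0];
      if (cvdim == 2) grad[1] = gx[1];
    }
    return out;
  }

  double value(const double* s, double* grad) const {
    return grid_mode ? grid_value(s, grad) : kernel_sum_value(s, grad);
  }

  void deposit(const double* s, double t) {
    double v_here = value(s, nullptr);
    double h_eff = height;
    if (bias_factor > 1.0) {
      h_eff = height * std::exp(-v_here / (KB * temperature * (bias_factor - 1.0)));
    }
    kc0.push_back(s[0]);
    kc1.push_back(cvdim == 2 ? s[1] : 0.0);
    kh.push_back(h_eff);
    kt.push_back(t);
    if (!grid_mode) return;
    // add Gaussian to grids within +-5 sigma
    int lo_i[2], hi_i[2];
    for (int d = 0; d < cvdim; ++d) {
      double ext = 5.0 * width[d];
      lo_i[d] = (int)std::floor((s[d] - ext - lo[d]) / dx[d]) - 1;
      hi_i[d] = (int)std::ceil((s[d] + ext - lo[d]) / dx[d]) + 1;
      if (!per[d]) {
        lo_i[d] = std::max(0, lo_i[d]);
        hi_i[d] = std::min(nb[d] - 1, hi_i[d]);
      }
    }
    if (cvdim == 1) {
      for (int a = lo_i[0]; a <= hi_i[0]; ++a) {
        int ia = per[0] ? ((a % nb[0]) + nb[0]) % nb[0] : a;
        double sa = lo[0] + a * dx[0];
        double u = cvdisp(sa, s[0], 0);
        double e = u * u / (2.0 * width[0] * width[0]);
        if (e > 25.0) continue;
        double g = h_eff * std::exp(-e);
        V[ia] += g;
        G0[ia] += -g * u / (width[0] * width[0]);
      }
    } else {
      int n1 = nb[1];
      for (int a = lo_i[0]; a <= hi_i[0]; ++a) {
        int ia = per[0] ? ((a % nb[0]) + nb[0]) % nb[0] : a;
        double sa = lo[0] + a * dx[0];
        double u0 = cvdisp(sa, s[0], 0);
        double e0 = u0 * u0 / (2.0 * width[0] * width[0]);
        if (e0 > 25.0) continue;
        for (int b = lo_i[1]; b <= hi_i[1]; ++b) {
          int ib = per[1] ? ((b % nb[1]) + nb[1]) % nb[1] : b;
          double sb = lo[1] + b * dx[1];
          double u1 = cvdisp(sb, s[1], 1);
          double e = e0 + u1 * u1 / (2.0 * width[1] * width[1]);
          if (e > 25.0) continue;
          double g = h_eff * std::exp(-e);
          V[ia * n1 + ib] += g;
          G0[ia * n1 + ib] += -g * u0 / (width[0] * width[0]);
          G1[ia * n1 + ib] += -g * u1 / (width[1] * width[1]);
        }
      }
    }
  }
};

// ---------------------------------------------------------------------------
// parsing helpers

static std::vector<int> as_idx0(SEXP x) {
  IntegerVector v(x);
  std::vector<int> out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = v[i] - 1;  // R 1-based -> 0-based
  return out;
}

static void parse_system(const List& sys, std::vector<double>& pos,
                         std::vector<double>& vel, std::vector<double>& mass,
                         std::vector<double>& charge, std::vector<int>& type,
                         std::vector<char>& frozen, BoxDef& box, Topology& top,
                         int& n) {
  NumericMatrix P = sys["pos"];
  n = P.nrow();
  pos.resize(3 * n);
  vel.assign(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) pos[3 * i + k] = P(i, k);
  if (sys.containsElementNamed("vel") && !Rf_isNull(sys["vel"])) {
    NumericMatrix Vl = sys["vel"];
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) vel[3 * i + k] = Vl(i, k);
  }
  NumericVector m = sys["mass"], q = sys["charge"];
  IntegerVector ty = sys["type"];
  LogicalVector fz = sys["frozen"];
  mass.assign(m.begin(), m.end());
  charge.assign(q.begin(), q.end());
  type.resize(n);
  frozen.resize(n);
  for (int i = 0; i < n; ++i) {
    type[i] = ty[i] - 1;
    frozen[i] = fz[i] ? 1 : 0;
    if (frozen[i]) {
      vel[3 * i] = vel[3 * i + 1] = vel[3 * i + 2] = 0;
    }
  }
  NumericVector bx = sys["box"];
  LogicalVector pr = sys["periodic"];
  for (int k = 0; k < 3; ++k) {
    box.L[k] = bx[k];
    box.per[k] = pr[k];
  }
  if (sys.containsElementNamed("bonds") && !Rf_isNull(sys["bonds"])) {
    NumericMatrix B = sys["bonds"];
    for (int b = 0; b < B.nrow(); ++b) {
      top.b_i.push_back((int)B(b, 0) - 1);
      top.b_j.push_back((int)B(b, 1) - 1);
      top.b_r0.push_back(B(b, 2));
      top.b_k.push_back(B(b, 3));
    }
  }
  if (sys.containsElementNamed("angles") && !Rf_isNull(sys["angles"])) {
    NumericMatrix A = sys["angles"];
    for (int a = 0; a < A.nrow(); ++a) {
      top.a_i.push_back((int)A(a, 0) - 1);
      top.a_j.push_back((int)A(a, 1) - 1);
      top.a_k.push_back((int)A(a, 2) - 1);
      top.a_t0.push_back(A(a, 3));
      top.a_kt.push_back(A(a, 4));
    }
  }
  // exclusions: 1-2 from bonds, 1-3 from angles (and bond chains)
  std::vector<std::vector<int>> adj(n);
  for (size_t b = 0; b < top.b_i.size(); ++b) {
    adj[top.b_i[b]].push_back(top.b_j[b]);
    adj[top.b_j[b]].push_back(top.b_i[b]);
    top.excl.insert(pair_key(top.b_i[b], top.b_j[b], n));
  }
  for (int i = 0; i < n; ++i) {
    for (int j : adj[i]) {
      for (int k : adj[j]) {
        if (k != i) top.excl.insert(pair_key(i, k, n));
      }
    }
  }
}

static FFDef parse_ff(const List& ff, const std::vector<double>& mass) {
  FFDef f;
  NumericMatrix S = ff["sigma"], E = ff["eps"];
  f.ntype = S.nrow();
  f.sigma.resize(f.ntype * f.ntype);
  f.eps.resize(f.ntype * f.ntype);
  for (int i = 0; i < f.ntype; ++i)
    for (int j = 0; j < f.ntype; ++j) {
      f.sigma[i * f.ntype + j] = S(i, j);
      f.eps[i * f.ntype + j] = E(i, j);
    }
  f.rc = as<double>(ff["rc"]);
  f.eps_r = as<double>(ff["eps_r"]);
  f.lj_shift = ff.containsElementNamed("lj_shift") ? as<bool>(ff["lj_shift"]) : true;
  f.coul_shift = ff.containsElementNamed("coul_shift") ? as<bool>(ff["coul_shift"]) : true;
  f.has_wall = ff.containsElementNamed("wall") && !Rf_isNull(ff["wall"]);
  if (f.has_wall) {
    List w = ff["wall"];
    f.wall_eps = as<double>(w["eps"]);
    f.wall_sigma = as<double>(w["sigma"]);
    f.wall_zref = as<double>(w["zref"]);
  }
  f.has_restraint = ff.containsElementNamed("restraint") && !Rf_isNull(ff["restraint"]);
  if (f.has_restraint) {
    List r = ff["restraint"];
    f.res_z0 = as<double>(r["z0"]);
    f.res_kappa = as<double>(r["kappa"]);
    f.res_exp = as<int>(r["exp"]);
    f.res_group = as_idx0(r["group"]);
  }
  f.has_pull = ff.containsElementNamed("pull") && !Rf_isNull(ff["pull"]);
  if (f.has_pull) {
    List p = ff["pull"];
    NumericVector fv = p["force"];
    for (int k = 0; k < 3; ++k) f.pull_f[k] = fv[k];
    f.pull_group = as_idx0(p["group"]);
    f.pull_mass = 0;
    for (int idx : f.pull_group) f.pull_mass += mass[idx];
  }
  f.has_dwell = ff.containsElementNamed("double_well") && !Rf_isNull(ff["double_well"]);
  if (f.has_dwell) {
    List d = ff["double_well"];
    f.dw_h = as<double>(d["barrier"]);
    f.dw_a = as<double>(d["half_sep"]);
  }
  return f;
}

// ---------------------------------------------------------------------------
// single-point energy/forces (exposed)

// [[Rcpp::export]]
List energy_forces_cpp(List sys, List ff, bool use_neighbor_list = true) {
  std::vector<double> pos, vel, mass, charge;
  std::vector<int> type;
  std::vector<char> frozen;
  BoxDef box;
  Topology top;
  int n;
  parse_system(sys, pos, vel, mass, charge, type, frozen, box, top, n);
  FFDef f = parse_ff(ff, mass);
  NeighborList nl;
  nl.use_list = use_neighbor_list;
  if (use_neighbor_list) nl.build(pos, n, box, frozen, top, f.rc);
  std::vector<double> frc(3 * n);
  EnergyAcc en;
  compute_forces(pos, mass, charge, type, frozen, n, box, f, top, nl, frc, en);
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) F(i, k) = frc[3 * i + k];
  return List::create(
      _["energy"] = List::create(_["lj"] = en.lj, _["coulomb"] = en.coul,
                                 _["wall"] = en.wall, _["bonded"] = en.bonded,
                                 _["restraint"] = en.restraint,
                                 _["external"] = en.external,
                                 _["total"] = en.total()),
      _["forces"] = F);
}

// ---------------------------------------------------------------------------
// steepest-descent minimizer with backtracking (builder relaxation)

// [[Rcpp::export]]
NumericMatrix minimize_cpp(List sys, List ff, int max_steps = 500,
                           double fmax_tol = 10.0, double step0 = 0.01) {
  std::vector<double> pos, vel, mass, charge;
  std::vector<int> type;
  std::vector<char> frozen;
  BoxDef box;
  Topology top;
  int n;
  parse_system(sys, pos, vel, mass, charge, type, frozen, box, top, n);
  FFDef f = parse_ff(ff, mass);
  NeighborList nl;
  nl.build(pos, n, box, frozen, top, f.rc);
  std::vector<double> frc(3 * n), trial(3 * n);
  EnergyAcc en, en2;
  compute_forces(pos, mass, charge, type, frozen, n, box, f, top, nl, frc, en);
  double step = step0;
  for (int it = 0; it < max_steps; ++it) {
    double fmax = 0;
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      for (int k = 0; k < 3; ++k) fmax = std::max(fmax, std::fabs(frc[3 * i + k]));
    }
    if (fmax < fmax_tol) break;
    // displace along normalized force, capped at `step` nm
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < 3; ++k) {
        double d = frozen[i] ? 0.0 : frc[3 * i + k] / fmax * step;
        trial[3 * i + k] = pos[3 * i + k] + d;
      }
    }
    if (nl.stale(trial, n)) nl.build(trial, n, box, frozen, top, f.rc);
    compute_forces(trial, mass, charge, type, frozen, n, box, f, top, nl, frc, en2);
    if (en2.total() < en.total()) {
      pos = trial;
      en = en2;
      step = std::min(step * 1.2, 0.05);
    } else {
      step *= 0.5;
      if (step < 1e-6) break;
      if (nl.stale(pos, n)) nl.build(pos, n, box, frozen, top, f.rc);
      compute_forces(pos, mass, charge, type, frozen, n, box, f, top, nl, frc, en);
      continue;
    }
    compute_forces(pos, mass, charge, type, frozen, n, box, f, top, nl, frc, en);
  }
  NumericMatrix P(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) P(i, k) = pos[3 * i + k];
  return P;
}

// ---------------------------------------------------------------------------
// main run loop: Langevin leapfrog + optional metadynamics

// [[Rcpp::export]]
List run_engine_cpp(List sys, List ff, List integ, int n_steps, List output,
                    Nullable<List> metad = R_NilValue, double t0 = 0.0) {
  std::vector<double> pos, vel, mass, charge;
  std::vector<int> type;
  std::vector<char> frozen;
  BoxDef box;
  Topology top;
  int n;
  parse_system(sys, pos, vel, mass, charge, type, frozen, box, top, n);
  FFDef f = parse_ff(ff, mass);

  double dt = as<double>(integ["dt"]);
  double temperature = as<double>(integ["temperature"]);
  double gamma = as<double>(integ["gamma"]);
  uint32_t seed = (uint32_t)as<double>(integ["seed"]);
  bool noise = integ.containsElementNamed("noise") ? as<bool>(integ["noise"]) : true;

  int frame_stride = as<int>(output["frame_stride"]);
  int log_stride = as<int>(output["log_stride"]);

  // metadynamics setup
  MetaDState md;
  CVDef cv;
  bool do_metad = metad.isNotNull();
  int cv_stride = 10;
  bool stop_enabled = false;
  int stop_op = -1, stop_persist = 1, stop_check = 10;
  double stop_value = 0;
  if (do_metad) {
    List m(metad);
    std::string kind = as<std::string>(m["cv_kind"]);
    cv.kind = (kind == "com_x") ? 1 : (kind == "com_xy") ? 2 : 3;
    cv.group = as_idx0(m["group"]);
    cv.group_mass = 0;
    for (int idx : cv.group) cv.group_mass += mass[idx];
    if (cv.kind == 3) {
      cv.groupB = as_idx0(m["group_b"]);
      cv.r0 = as<double>(m["r0"]);
    }
    md.cvdim = cv.dim();
    md.height = as<double>(m["height"]);
    NumericVector w = m["width"];
    for (int d = 0; d < md.cvdim; ++d) md.width[d] = w[d % w.size()];
    md.stride = as<int>(m["stride"]);
    md.bias_factor = Rf_isNull(m["bias_factor"]) ? 0.0 : as<double>(m["bias_factor"]);
    md.temperature = temperature;
    md.grid_mode = as<bool>(m["grid_mode"]);
    if (md.grid_mode) {
      NumericVector glo = m["grid_min"], ghi = m["grid_max"];
      IntegerVector gnb = m["grid_bins"];
      LogicalVector gper = m["grid_periodic"];
      for (int d = 0; d < md.cvdim; ++d) {
        md.lo[d] = glo[d];
        md.hi[d] = ghi[d];
        md.nb[d] = gnb[d];
        md.per[d] = gper[d];
      }
      md.init_grid();
    }
    // pre-existing kernels (multiple walkers / restart)
    if (m.containsElementNamed("kernels") && !Rf_isNull(m["kernels"])) {
      NumericMatrix K = m["kernels"];  // c0 [, c1], height, time
      for (int i = 0; i < K.nrow(); ++i) {
        double s[2] = {K(i, 0), md.cvdim == 2 ? K(i, 1) : 0.0};
        double h = K(i, md.cvdim);
        double tk = K(i, md.cvdim + 1);
        md.kc0.push_back(s[0]);
        md.kc1.push_back(s[1]);
        md.kh.push_back(h);
        md.kt.push_back(tk);
        if (md.grid_mode) {
          // replay directly onto grid at stored (already damped) height
          double save_h = md.height, save_bf = md.bias_factor;
          md.height = h;
          md.bias_factor = 0;
          md.kc0.pop_back(); md.kc1.pop_back(); md.kh.pop_back(); md.kt.pop_back();
          md.deposit(s, tk);
          md.height = save_h;
          md.bias_factor = save_bf;
        }
      }
    }
    cv_stride = as<int>(m["cv_stride"]);
    if (m.containsElementNamed("stop") && !Rf_isNull(m["stop"])) {
      List st = m["stop"];
      stop_enabled = true;
      stop_op = as<std::string>(st["op"]) == "gt" ? 1 : -1;
      stop_value = as<double>(st["value"]);
      stop_persist = as<int>(st["persistence"]);
      stop_check = as<int>(st["check_stride"]);
    }
  }

  NeighborList nl;
  nl.build(pos, n, box, frozen, top, f.rc);
  std::vector<double> frc(3 * n);
  EnergyAcc en;

  std::mt19937_64 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  double a_damp = std::exp(-gamma * dt);
  std::vector<double> noise_sd(n);
  for (int i = 0; i < n; ++i) {
    noise_sd[i] = frozen[i] || mass[i] <= 0
                      ? 0.0
                      : std::sqrt((1.0 - a_damp * a_damp) * KB * temperature / mass[i]);
  }

  // output accumulators
  std::vector<double> frame_times;
  std::vector<NumericMatrix> frames;
  std::vector<double> elog;  // rows of 9
  std::vector<double> cvlog;  // rows of (1 + cvdim + 1)
  int n_mobile = 0;
  for (int i = 0; i < n; ++i) if (!frozen[i]) ++n_mobile;
  double ndf = 3.0 * n_mobile;

  // acceleration-factor accumulation: streaming logsumexp of beta*V
  double lse = -INFINITY;
  long n_lse = 0;
  double beta = 1.0 / (KB * temperature);
  auto lse_add = [&](double b) {
    if (b > lse) {
      lse = b + std::log1p(lse == -INFINITY ? 0.0 : std::exp(lse - b));
    } else {
      lse = lse + std::log1p(std::exp(b - lse));
    }
    ++n_lse;
  };

  bool stopped = false, unstable = false;
  int stop_step = -1, persist_count = 0;
  double max_disp_lim = 0.5 * f.rc;

  auto record_frame = [&](double t) {
    NumericMatrix P(n, 3);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) P(i, k) = pos[3 * i + k];
    frames.push_back(P);
    frame_times.push_back(t);
  };

  auto record_energy = [&](double t) {
    // synchronize leapfrog velocities to the full step with a half kick
    double ke = 0;
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      for (int k = 0; k < 3; ++k) {
        double v = vel[3 * i + k] + 0.5 * dt * frc[3 * i + k] / mass[i];
        ke += 0.5 * mass[i] * v * v;
      }
    }
    double tkin = ndf > 0 ? 2.0 * ke / (ndf * KB) : 0.0;
    double row[9] = {t, en.lj, en.coul, en.wall, en.bonded, en.restraint,
                     en.external, ke, tkin};
    elog.insert(elog.end(), row, row + 9);
  };

  double s[2] = {0, 0}, dVds[2] = {0, 0};
  double Vcur = 0;

  // initial force evaluation
  compute_forces(pos, mass, charge, type, frozen, n, box, f, top, nl, frc, en);
  if (do_metad) {
    cv_value(pos, mass, cv, s);
    Vcur = md.value(s, dVds);
    cv_apply_bias_force(pos, mass, cv, dVds, frc);
  }
  record_frame(t0);
  record_energy(t0);
  if (do_metad) {
    double row[4] = {t0, s[0], md.cvdim == 2 ? s[1] : Vcur, Vcur};
    cvlog.insert(cvlog.end(), row, row + (2 + md.cvdim));
    lse_add(beta * Vcur);
  }

  for (int step = 1; step <= n_steps; ++step) {
    double t = t0 + step * dt;
    // leapfrog Langevin: v <- a*v + (F/m)*dt + sigma*xi ; x <- x + v*dt
    double maxd2 = 0;
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      for (int k = 0; k < 3; ++k) {
        double v = a_damp * vel[3 * i + k] + frc[3 * i + k] / mass[i] * dt;
        if (noise) v += noise_sd[i] * gauss(rng);
        vel[3 * i + k] = v;
        double d = v * dt;
        pos[3 * i + k] += d;
        maxd2 = std::max(maxd2, d * d);
      }
      // reflecting z boundaries (z is non-periodic)
      double zmin = f.has_wall ? f.wall_zref + 0.05 : 0.0;
      bool reflect_lo = f.has_wall;
      double& z = pos[3 * i + 2];
      if (reflect_lo && z < zmin) {
        z = 2 * zmin - z;
        vel[3 * i + 2] = -vel[3 * i + 2];
      }
      if (!box.per[2] && box.L[2] > 0 && z > box.L[2]) {
        z = 2 * box.L[2] - z;
        vel[3 * i + 2] = -vel[3 * i + 2];
      }
    }
    if (maxd2 > max_disp_lim * max_disp_lim) {
      unstable = true;
      stop_step = step;
      break;
    }
    if (nl.use_list && nl.stale(pos, n)) nl.build(pos, n, box, frozen, top, f.rc);

    compute_forces(pos, mass, charge, type, frozen, n, box, f, top, nl, frc, en);

    if (do_metad) {
      cv_value(pos, mass, cv, s);
      // deposit before evaluating bias force so the new kernel acts at once
      if (md.stride > 0 && step % md.stride == 0) {
        md.deposit(s, t);
      }
      Vcur = md.value(s, dVds);
      cv_apply_bias_force(pos, mass, cv, dVds, frc);
      lse_add(beta * Vcur);
      if (step % cv_stride == 0) {
        double row[4] = {t, s[0], md.cvdim == 2 ? s[1] : Vcur, Vcur};
        cvlog.insert(cvlog.end(), row, row + (2 + md.cvdim));
      }
      if (stop_enabled && step % stop_check == 0) {
        bool cond = stop_op > 0 ? (s[0] > stop_value) : (s[0] < stop_value);
        persist_count = cond ? persist_count + 1 : 0;
        if (persist_count >= stop_persist) {
          stopped = true;
          stop_step = step;
          record_frame(t);
          record_energy(t);
          break;
        }
      }
    }

    if (step % frame_stride == 0 && !(stopped && stop_step == step)) record_frame(t);
    if (step % log_stride == 0) record_energy(t);
  }

  // pack outputs
  int ne = elog.size() / 9;
  NumericMatrix EL(ne, 9);
  for (int r = 0; r < ne; ++r)
    for (int c = 0; c < 9; ++c) EL(r, c) = elog[r * 9 + c];
  colnames(EL) = CharacterVector::create("time", "lj", "coulomb", "wall",
                                         "bonded", "restraint", "external",
                                         "kinetic", "temperature");

  NumericMatrix P(n, 3), Vm(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      P(i, k) = pos[3 * i + k];
      Vm(i, k) = vel[3 * i + k];
    }

  List out = List::create(
      _["pos"] = P, _["vel"] = Vm, _["frames"] = wrap(frames),
      _["frame_times"] = wrap(frame_times), _["energies"] = EL,
      _["stopped"] = stopped, _["unstable"] = unstable,
      _["stop_step"] = stop_step, _["final_time"] = t0 + (stop_step > 0 ? stop_step : n_steps) * dt);

  if (do_metad) {
    int ncv = 2 + md.cvdim;
    int nr = cvlog.size() / ncv;
    NumericMatrix CL(nr, ncv);
    for (int r = 0; r < nr; ++r)
      for (int c = 0; c < ncv; ++c) CL(r, c) = cvlog[r * ncv + c];
    size_t nk = md.kh.size();
    NumericMatrix K(nk, md.cvdim + 2);
    for (size_t i = 0; i < nk; ++i) {
      K(i, 0) = md.kc0[i];
      if (md.cvdim == 2) K(i, 1) = md.kc1[i];
      K(i, md.cvdim) = md.kh[i];
      K(i, md.cvdim + 1) = md.kt[i];
    }
    out["cv_log"] = CL;
    out["kernels"] = K;
    out["log_mean_expbetaV"] = lse - std::log((double)n_lse);
    if (md.grid_mode) {
      out["bias_grid"] = wrap(md.V);
      out["grid_dim"] = IntegerVector::create(md.nb[0], md.cvdim == 2 ? md.nb[1] : 1);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// contacts helpers for observables

// [[Rcpp::export]]
NumericVector switched_contacts_cpp(NumericMatrix A, NumericMatrix B, double r0) {
  int na = A.nrow(), nb = B.nrow();
  double tot = 0;
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j) {
      double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1), dz = A(i, 2) - B(j, 2);
      double x6 = std::pow((dx * dx + dy * dy + dz * dz) / (r0 * r0), 3.0);
      tot += 1.0 / (1.0 + x6);
    }
  return NumericVector::create(tot);
}

// per-row-of-A count of B beads within cutoff
// [[Rcpp::export]]
IntegerVector count_within_cpp(NumericMatrix A, NumericMatrix B, double cutoff) {
  int na = A.nrow(), nb = B.nrow();
  double c2 = cutoff * cutoff;
  IntegerVector out(na);
  for (int i = 0; i < na; ++i) {
    int cnt = 0;
    for (int j = 0; j < nb; ++j) {
      double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1), dz = A(i, 2) - B(j, 2);
      if (dx * dx + dy * dy + dz * dz < c2) ++cnt;
    }
    out[i] = cnt;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Shrake-Rupley SASA with Fibonacci sphere points

// [[Rcpp::export]]
NumericVector sasa_cpp(NumericMatrix pos, NumericVector radius, double probe,
                       int n_points) {
  int n = pos.nrow();
  // Fibonacci sphere
  std::vector<double> sx(n_points), sy(n_points), sz(n_points);
  double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int i = 0; i < n_points; ++i) {
    double z = 1.0 - 2.0 * (i + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = ga * i;
    sx[i] = r * std::cos(th);
    sy[i] = r * std::sin(th);
    sz[i] = z;
  }
  NumericVector area(n);
  for (int i = 0; i < n; ++i) {
    double ri = radius[i] + probe;
    // neighbors that can occlude
    std::vector<int> nbr;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1),
             dz = pos(i, 2) - pos(j, 2);
      double rj = radius[j] + probe;
      double lim = ri + rj;
      if (dx * dx + dy * dy + dz * dz < lim * lim) nbr.push_back(j);
    }
    int acc = 0;
    for (int p = 0; p < n_points; ++p) {
      double px = pos(i, 0) + ri * sx[p];
      double py = pos(i, 1) + ri * sy[p];
      double pz = pos(i, 2) + ri * sz[p];
      bool buried = false;
      for (int j : nbr) {
        double rj = radius[j] + probe;
        double dx = px - pos(j, 0), dy = py - pos(j, 1), dz = pz - pos(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) {
          buried = true;
          break;
        }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * acc / n_points;
  }
  return area;
}
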