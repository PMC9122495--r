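// Desk-scale CG force field and Langevin integrator.
//
// Units: coordinates nm, energy kcal/mol, mass g/mol, time fs.
// Bond/spring constants arrive in kcal/mol/A^2 and are converted to
// kcal/mol/nm^2 (x100) here; the bond energy convention is k (r - r0)^2
// (no 1/2 prefactor).  The nonbonded potential is a WCA repulsive core
// plus a smooth cosine-squared attractive well whose depth and force
// scale linearly with the pair's scaling factor.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static const double MVV2E = 239005.736; // (g/mol)(nm/fs)^2 -> kcal/mol
static const double KB = 0.0019872041;  // kcal/mol/K

// ---------------------------------------------------------------- potential

struct PairPot {
  double sigma, eps_rep, eps_att, rc, rmin;
  PairPot(double s, double er, double ea, double rc_)
      : sigma(s), eps_rep(er), eps_att(ea), rc(rc_),
        rmin(std::pow(2.0, 1.0 / 6.0) * s) {}
  // energy and radial force magnitude (F = -dE/dr) at distance r for
  // attraction scaling factor f
  inline void eval(double r, double f, double &e, double &fr) const {
    e = 0.0;
    fr = 0.0;
    if (r < rmin) {
      double sr6 = std::pow(sigma / r, 6), sr12 = sr6 * sr6;
      e += 4.0 * eps_rep * (sr12 - sr6) + eps_rep;
      fr += 4.0 * eps_rep * (12.0 * sr12 - 6.0 * sr6) / r;
      e += -f * eps_att;
    } else if (r < rc) {
      double up = (M_PI / 2.0) / (rc - rmin);
      double u = up * (r - rmin);
      double c = std::cos(u);
      e += -f * eps_att * c * c;
      fr += -f * eps_att * std::sin(2.0 * u) * up;
    }
  }
};

// [[Rcpp::export]]
List pair_potential_cpp(NumericVector r, double factor, double sigma,
                        double eps_rep, double eps_att, double cutoff) {
  PairPot pot(sigma, eps_rep, eps_att, cutoff);
  int n = r.size();
  NumericVector e(n), f(n);
  for (int i = 0; i < n; ++i) {
    if (r[i] <= 0) stop("pair potential undefined at r <= 0");
    pot.eval(r[i], factor, e[i], f[i]);
  }
  return List::create(_["energy"] = e, _["force"] = f);
}

// ------------------------------------------------------------------- helpers

static inline double minimg(double d, double L) {
  return d - L * std::round(d / L);
}

struct Topo {
  std::vector<int> bi, bj, ai, aj, al;
  std::vector<double> bk, br0, ak, ath0;
  std::unordered_set<int64_t> excl;
  int n;
  void addpairs(IntegerVector i, IntegerVector j, NumericVector k,
                NumericVector r0) {
    for (int s = 0; s < i.size(); ++s) {
      bi.push_back(i[s] - 1);
      bj.push_back(j[s] - 1);
      bk.push_back(k[s] * 100.0); // kcal/mol/A^2 -> /nm^2
      br0.push_back(r0[s]);
      int a = i[s] - 1, b = j[s] - 1;
      if (a > b) std::swap(a, b);
      excl.insert((int64_t)a * n + b);
    }
  }
};

class ForceField {
public:
  PairPot pot;
  NumericMatrix fmat;
  std::vector<int> cls, mol;
  std::vector<char> isprot;
  std::vector<double> box;
  bool periodic;
  Topo topo;
  bool use_cells;

  ForceField(PairPot p, NumericMatrix fm, IntegerVector cls_,
             IntegerVector mol_, LogicalVector isprot_, NumericVector box_,
             bool cells)
      : pot(p), fmat(fm), use_cells(cells) {
    int n = cls_.size();
    cls.assign(cls_.begin(), cls_.end());
    mol.assign(mol_.begin(), mol_.end());
    isprot.resize(n);
    for (int i = 0; i < n; ++i) isprot[i] = isprot_[i] ? 1 : 0;
    periodic = box_.size() == 3;
    if (periodic) box.assign(box_.begin(), box_.end());
    topo.n = n;
  }

  void addtopo(List bonds, List angles, List springs) {
    topo.addpairs(bonds["i"], bonds["j"], bonds["k"], bonds["r0"]);
    topo.addpairs(springs["i"], springs["j"], springs["k"], springs["r0"]);
    IntegerVector ai = angles["i"], aj = angles["j"], al = angles["l"];
    NumericVector ak = angles["k"], ath0 = angles["theta0"];
    int nb = topo.bi.size(); // bonds+springs recorded; angles go separately
    (void)nb;
    for (int s = 0; s < ai.size(); ++s) {
      topo.ai.push_back(ai[s] - 1);
      topo.aj.push_back(aj[s] - 1);
      topo.al.push_back(al[s] - 1);
      topo.ak.push_back(ak[s]); // already kcal/mol/rad^2
      topo.ath0.push_back(ath0[s]);
    }
  }

  inline bool skip(int i, int j) const {
    if (mol[i] == mol[j]) return true;
    if (isprot[i] && isprot[j]) return true;
    int a = i, b = j;
    if (a > b) std::swap(a, b);
    return topo.excl.count((int64_t)a * topo.n + b) > 0;
  }

  inline void pair_one(const std::vector<double> &x, int i, int j,
                       std::vector<double> &F, double &epot) {
    double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
           dz = x[3 * i + 2] - x[3 * j + 2];
    if (periodic) {
      dx = minimg(dx, box[0]);
      dy = minimg(dy, box[1]);
      dz = minimg(dz, box[2]);
    }
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= pot.rc * pot.rc) return;
    if (skip(i, j)) return;
    double r = std::sqrt(r2);
    if (r < 0.05)
      stop("beads %d and %d overlap (r = %g nm) below the table range",
           i + 1, j + 1, r);
    double f = fmat(cls[i], cls[j]);
    double e, fr;
    pot.eval(r, f, e, fr);
    epot += e;
    double s = fr / r;
    F[3 * i] += s * dx;
    F[3 * i + 1] += s * dy;
    F[3 * i + 2] += s * dz;
    F[3 * j] -= s * dx;
    F[3 * j + 1] -= s * dy;
    F[3 * j + 2] -= s * dz;
  }

  void nonbonded(const std::vector<double> &x, std::vector<double> &F,
                 double &epot) {
    int n = topo.n;
    if (!use_cells || !periodic) {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) pair_one(x, i, j, F, epot);
      return;
    }
    // cell list
    int ncx = std::max(1, (int)(box[0] / pot.rc));
    int ncy = std::max(1, (int)(box[1] / pot.rc));
    int ncz = std::max(1, (int)(box[2] / pot.rc));
    if (ncx < 3 || ncy < 3 || ncz < 3) { // too few cells: all pairs
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) pair_one(x, i, j, F, epot);
      return;
    }
    std::vector<int> head(ncx * ncy * ncz, -1), next(n, -1), cellof(n);
    for (int i = 0; i < n; ++i) {
      double xi = x[3 * i] - box[0] * std::floor(x[3 * i] / box[0]);
      double yi = x[3 * i + 1] - box[1] * std::floor(x[3 * i + 1] / box[1]);
      double zi = x[3 * i + 2] - box[2] * std::floor(x[3 * i + 2] / box[2]);
      int cx = std::min(ncx - 1, (int)(xi / box[0] * ncx));
      int cy = std::min(ncy - 1, (int)(yi / box[1] * ncy));
      int cz = std::min(ncz - 1, (int)(zi / box[2] * ncz));
      int c = (cz * ncy + cy) * ncx + cx;
      cellof[i] = c;
      next[i] = head[c];
      head[c] = i;
    }
    for (int cz = 0; cz < ncz; ++cz)
      for (int cy = 0; cy < ncy; ++cy)
        for (int cx = 0; cx < ncx; ++cx) {
          int c = (cz * ncy + cy) * ncx + cx;
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                int nx = (cx + dx + ncx) % ncx, ny = (cy + dy + ncy) % ncy,
                    nz = (cz + dz + ncz) % ncz;
                int c2 = (nz * ncy + ny) * ncx + nx;
                if (c2 < c) continue;
                for (int i = head[c]; i >= 0; i = next[i])
                  for (int j = (c2 == c ? next[i] : head[c2]); j >= 0;
                       j = next[j])
                    pair_one(x, i, j, F, epot);
              }
        }
  }

  void bonded(const std::vector<double> &x, std::vector<double> &F,
              double &epot) {
    // bonds and elastic springs: k (r - r0)^2
    for (size_t s = 0; s < topo.bi.size(); ++s) {
      int i = topo.bi[s], j = topo.bj[s];
      double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
             dz = x[3 * i + 2] - x[3 * j + 2];
      if (periodic) {
        dx = minimg(dx, box[0]);
        dy = minimg(dy, box[1]);
        dz = minimg(dz, box[2]);
      }
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dr = r - topo.br0[s];
      epot += topo.bk[s] * dr * dr;
      double fs = -2.0 * topo.bk[s] * dr / r;
      F[3 * i] += fs * dx;
      F[3 * i + 1] += fs * dy;
      F[3 * i + 2] += fs * dz;
      F[3 * j] -= fs * dx;
      F[3 * j + 1] -= fs * dy;
      F[3 * j + 2] -= fs * dz;
    }
    // harmonic angles: k (theta - theta0)^2, apex j
    for (size_t s = 0; s < topo.ai.size(); ++s) {
      int i = topo.ai[s], j = topo.aj[s], l = topo.al[s];
      double ax = x[3 * i] - x[3 * j], ay = x[3 * i + 1] - x[3 * j + 1],
             az = x[3 * i + 2] - x[3 * j + 2];
      double bx = x[3 * l] - x[3 * j], by = x[3 * l + 1] - x[3 * j + 1],
             bz = x[3 * l + 2] - x[3 * j + 2];
      if (periodic) {
        ax = minimg(ax, box[0]); ay = minimg(ay, box[1]); az = minimg(az, box[2]);
        bx = minimg(bx, box[0]); by = minimg(by, box[1]); bz = minimg(bz, box[2]);
      }
      double ra = std::sqrt(ax * ax + ay * ay + az * az);
      double rb = std::sqrt(bx * bx + by * by + bz * bz);
      double c = (ax * bx + ay * by + az * bz) / (ra * rb);
      c = std::max(-1.0, std::min(1.0, c));
      double th = std::acos(c);
      double dth = th - topo.ath0[s];
      epot += topo.ak[s] * dth * dth;
      double st = std::sqrt(std::max(1e-12, 1.0 - c * c));
      double coef = 2.0 * topo.ak[s] * dth / st;
      // force on i = coef * d(cos)/dxi etc.
      double fi_x = coef * (bx / (ra * rb) - c * ax / (ra * ra));
      double fi_y = coef * (by / (ra * rb) - c * ay / (ra * ra));
      double fi_z = coef * (bz / (ra * rb) - c * az / (ra * ra));
      double fl_x = coef * (ax / (ra * rb) - c * bx / (rb * rb));
      double fl_y = coef * (ay / (ra * rb) - c * by / (rb * rb));
      double fl_z = coef * (az / (ra * rb) - c * bz / (rb * rb));
      F[3 * i] += fi_x; F[3 * i + 1] += fi_y; F[3 * i + 2] += fi_z;
      F[3 * l] += fl_x; F[3 * l + 1] += fl_y; F[3 * l + 2] += fl_z;
      F[3 * j] -= fi_x + fl_x;
      F[3 * j + 1] -= fi_y + fl_y;
      F[3 * j + 2] -= fi_z + fl_z;
    }
  }

  double all(const std::vector<double> &x, std::vector<double> &F) {
    std::fill(F.begin(), F.end(), 0.0);
    double epot = 0.0;
    nonbonded(x, F, epot);
    bonded(x, F, epot);
    return epot;
  }
};

static ForceField make_ff(NumericMatrix x, IntegerVector mol,
                          LogicalVector isprot, IntegerVector cls,
                          NumericMatrix fmat, List potpar, NumericVector box,
                          List bonds, List angles, List springs,
                          bool use_cells) {
  PairPot pot(as<double>(potpar["sigma"]), as<double>(potpar["eps_rep"]),
              as<double>(potpar["eps_att"]), as<double>(potpar["cutoff"]));
  ForceField ff(pot, fmat, cls, mol, isprot, box, use_cells);
  ff.addtopo(bonds, angles, springs);
  return ff;
}

// ---------------------------------------------------------- counter-based RNG

static inline uint64_t splitmix64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

static inline double gauss_noise(uint64_t seed, uint64_t step, uint64_t bead,
                                 uint64_t axis) {
  uint64_t key = splitmix64(seed ^ splitmix64(step ^ splitmix64(
                     bead ^ splitmix64(axis + 0x1234abcdULL))));
  uint64_t k2 = splitmix64(key);
  double u1 = ((key >> 11) + 1.0) / 9007199254740994.0; // (0,1)
  double u2 = (k2 >> 11) / 9007199254740992.0;          // [0,1)
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
}

// ------------------------------------------------------------------ exports

// [[Rcpp::export]]
List cg_forces_cpp(NumericMatrix x, IntegerVector mol, LogicalVector isprot,
                   IntegerVector cls, NumericMatrix fmat, List potpar,
                   NumericVector box, List bonds, List angles, List springs,
                   bool use_cells) {
  ForceField ff = make_ff(x, mol, isprot, cls, fmat, potpar, box, bonds,
                          angles, springs, use_cells);
  int n = x.nrow();
  std::vector<double> xx(3 * n), F(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) xx[3 * i + d] = x(i, d);
  double epot = ff.all(xx, F);
  NumericMatrix Fm(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) Fm(i, d) = F[3 * i + d];
  return List::create(_["forces"] = Fm, _["epot"] = epot);
}

// [[Rcpp::export]]
List cg_run_cpp(NumericMatrix x, NumericMatrix v, NumericVector mass,
                IntegerVector mol, LogicalVector isprot, IntegerVector cls,
                NumericMatrix fmat, List potpar, NumericVector box,
                List bonds, List angles, List springs, double dt,
                double temperature, double damping, int seed, int nsteps,
                int stride, int step0, bool use_cells) {
  ForceField ff = make_ff(x, mol, isprot, cls, fmat, potpar, box, bonds,
                          angles, springs, use_cells);
  int n = x.nrow();
  std::vector<double> xx(3 * n), vv(3 * n), F(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      xx[3 * i + d] = x(i, d);
      vv[3 * i + d] = v(i, d);
    }
  double epot = ff.all(xx, F);

  bool thermo = damping > 0 && R_finite(damping);
  double c1 = thermo ? std::exp(-dt / damping) : 1.0;
  double c2 = thermo ? std::sqrt(1.0 - c1 * c1) : 0.0;

  int nstore = nsteps / stride;
  NumericVector epots(nstore), ekins(nstore), temps(nstore);
  // stored frames
  std::vector<double> traj((size_t)nstore * n * 3);

  int isto = 0;
  for (int step = 1; step <= nsteps; ++step) {
    uint64_t gstep = (uint64_t)(step0 + step);
    // B: half kick
    for (int i = 0; i < n; ++i) {
      double a = dt * 0.5 / (mass[i] * MVV2E);
      vv[3 * i] += a * F[3 * i];
      vv[3 * i + 1] += a * F[3 * i + 1];
      vv[3 * i + 2] += a * F[3 * i + 2];
    }
    // A: half drift
    for (int k = 0; k < 3 * n; ++k) xx[k] += 0.5 * dt * vv[k];
    // O: Ornstein-Uhlenbeck
    if (thermo) {
      for (int i = 0; i < n; ++i) {
        double vth = std::sqrt(KB * temperature / (mass[i] * MVV2E));
        for (int d = 0; d < 3; ++d)
          vv[3 * i + d] = c1 * vv[3 * i + d] +
                          c2 * vth * gauss_noise((uint64_t)seed, gstep,
                                                 (uint64_t)i, (uint64_t)d);
      }
    }
    // A: half drift
    for (int k = 0; k < 3 * n; ++k) xx[k] += 0.5 * dt * vv[k];
    // force update + B: half kick
    epot = ff.all(xx, F);
    for (int i = 0; i < n; ++i) {
      double a = dt * 0.5 / (mass[i] * MVV2E);
      vv[3 * i] += a * F[3 * i];
      vv[3 * i + 1] += a * F[3 * i + 1];
      vv[3 * i + 2] += a * F[3 * i + 2];
    }
    for (int k = 0; k < 3 * n; ++k)
      if (!std::isfinite(xx[k]))
        stop("non-finite coordinates at step %d: integration blew up",
             step0 + step);
    if (step % stride == 0) {
      double ke = 0.0;
      for (int i = 0; i < n; ++i)
        ke += 0.5 * mass[i] *
              (vv[3 * i] * vv[3 * i] + vv[3 * i + 1] * vv[3 * i + 1] +
               vv[3 * i + 2] * vv[3 * i + 2]) * MVV2E;
      epots[isto] = epot;
      ekins[isto] = ke;
      temps[isto] = 2.0 * ke / (3.0 * n * KB);
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          traj[((size_t)isto * n + i) * 3 + d] = xx[3 * i + d];
      ++isto;
    }
  }

  NumericMatrix xout(n, 3), vout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      xout(i, d) = xx[3 * i + d];
      vout(i, d) = vv[3 * i + d];
    }
  NumericVector trj(traj.begin(), traj.end());
  trj.attr("dim") = IntegerVector::create(3, n, nstore);
  return List::create(_["x"] = xout, _["v"] = vout, _["traj"] = trj,
                      _["epot"] = epots, _["ekin"] = ekins,
                      _["temperature"] = temps,
                      _["steps_done"] = step0 + nsteps);
}
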