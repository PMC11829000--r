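// Compiled core: coarse-grained force field, BAOAB Langevin propagation,
// Bayesian distance-restraint (metainference) energy with Gibbs-sampled
// error parameters, parallel-bias well-tempered metadynamics, and small
// geometry kernels (Kabsch RMSD, pairwise distances).
//
// Units: coordinates nm, time ps, energy kJ/mol, mass amu, temperature K.
// Metainference error parameters and deviations are kept in Angstrom to
// match the distogram scale; the ratio entering the energy is dimensionless.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <random>
#include <sstream>

using namespace Rcpp;

static const double KB = 0.00831446261815324; // kJ/mol/K

// ---------------------------------------------------------------------------
// RNG: mt19937_64 + explicit Box-Muller so the stream is fully owned here.
// ---------------------------------------------------------------------------
struct Rng {
  std::mt19937_64 eng;
  bool have_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) : eng(seed) {}
  double unif() { // in (0,1)
    return (static_cast<double>(eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    have_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

// ---------------------------------------------------------------------------
// Topology / force field
// ---------------------------------------------------------------------------
struct Topo {
  int n;
  std::vector<double> sigma, lambda, charge, mass;
  double bond_k, bond_r0;
  double ah_eps, ah_rc, dh_rc, dh_pref, kappa;
  bool use_dh;
};

static Topo topo_from_list(const List& tl) {
  Topo t;
  t.sigma  = as<std::vector<double>>(tl["sigma"]);
  t.lambda = as<std::vector<double>>(tl["lambda"]);
  t.charge = as<std::vector<double>>(tl["charge"]);
  t.mass   = as<std::vector<double>>(tl["mass"]);
  t.n = (int)t.sigma.size();
  t.bond_k  = as<double>(tl["bond_k"]);
  t.bond_r0 = as<double>(tl["bond_r0"]);
  t.ah_eps  = as<double>(tl["ah_eps"]);
  t.ah_rc   = as<double>(tl["ah_rc"]);
  t.dh_rc   = as<double>(tl["dh_rc"]);
  t.dh_pref = as<double>(tl["dh_pref"]);
  t.kappa   = as<double>(tl["kappa"]);
  t.use_dh  = as<bool>(tl["use_dh"]);
  return t;
}

// Ashbaugh-Hatch pair energy/force magnitude (dU/dr), truncated & shifted.
static inline void ah_pair(double r, double sij, double lij, double eps,
                           double rc, double& u, double& dudr) {
  u = 0.0; dudr = 0.0;
  if (r >= rc) return;
  double sr6 = std::pow(sij / r, 6), sr12 = sr6 * sr6;
  double lj = 4.0 * eps * (sr12 - sr6);
  double dlj = 4.0 * eps * (-12.0 * sr12 + 6.0 * sr6) / r;
  double src6 = std::pow(sij / rc, 6), src12 = src6 * src6;
  double ljrc = 4.0 * eps * (src12 - src6); // rc > 2^(1/6) sigma always holds here
  double rmin = std::pow(2.0, 1.0 / 6.0) * sij;
  if (r <= rmin) {
    u = lj + (1.0 - lij) * eps - lij * ljrc;
    dudr = dlj;
  } else {
    u = lij * (lj - ljrc);
    dudr = lij * dlj;
  }
}

// Full CG energy + forces. coords length 3n (x0,y0,z0,x1,...). Returns E.
static double cg_energy_forces(const std::vector<double>& x, const Topo& t,
                               std::vector<double>* f) {
  const int n = t.n;
  if (f) std::fill(f->begin(), f->end(), 0.0);
  double e = 0.0;
  const double rfloor = 1e-3; // keeps energies finite for the minimizer
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1], dz = x[3*i+2] - x[3*j+2];
      double r2 = dx*dx + dy*dy + dz*dz;
      double r = std::sqrt(r2);
      if (r < rfloor) r = rfloor;
      double u = 0.0, dudr = 0.0;
      if (j == i + 1) {
        double d = r - t.bond_r0;
        u = 0.5 * t.bond_k * d * d;
        dudr = t.bond_k * d;
      } else {
        double sij = 0.5 * (t.sigma[i] + t.sigma[j]);
        double lij = 0.5 * (t.lambda[i] + t.lambda[j]);
        double ua, dua;
        ah_pair(r, sij, lij, t.ah_eps, t.ah_rc, ua, dua);
        u += ua; dudr += dua;
        if (t.use_dh && t.charge[i] != 0.0 && t.charge[j] != 0.0 && r < t.dh_rc) {
          double qq = t.dh_pref * t.charge[i] * t.charge[j];
          double ud = qq * (std::exp(-t.kappa * r) / r -
                            std::exp(-t.kappa * t.dh_rc) / t.dh_rc);
          double dud = -qq * std::exp(-t.kappa * r) * (t.kappa * r + 1.0) / r2;
          u += ud; dudr += dud;
        }
      }
      e += u;
      if (f) {
        double fac = -dudr / r;
        (*f)[3*i]   += fac * dx; (*f)[3*i+1] += fac * dy; (*f)[3*i+2] += fac * dz;
        (*f)[3*j]   -= fac * dx; (*f)[3*j+1] -= fac * dy; (*f)[3*j+2] -= fac * dz;
      }
    }
  }
  return e;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix coords, List topo) {
  Topo t = topo_from_list(topo);
  int n = t.n;
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3*i+k] = coords(i, k);
  double e = cg_energy_forces(x, t, &f);
  NumericMatrix fm(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) fm(i, k) = f[3*i+k];
  return List::create(_["energy"] = e, _["forces"] = fm);
}

// Steepest descent with adaptive step; returns minimized coords.
// [[Rcpp::export]]
List cpp_minimize(NumericMatrix coords, List topo, int max_steps) {
  Topo t = topo_from_list(topo);
  int n = t.n;
  std::vector<double> x(3 * n), f(3 * n), xt(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3*i+k] = coords(i, k);
  double e = cg_energy_forces(x, t, &f);
  double gamma = 1e-5;
  int accepted = 0;
  for (int s = 0; s < max_steps; ++s) {
    double fmax = 0.0;
    for (double v : f) fmax = std::max(fmax, std::fabs(v));
    if (fmax < 1e-8) break;
    double scale = gamma / std::max(1.0, fmax * gamma / 0.05); // cap displacement 0.05 nm
    for (int k = 0; k < 3 * n; ++k) xt[k] = x[k] + scale * f[k];
    double et = cg_energy_forces(xt, t, nullptr);
    if (et < e) {
      x = xt; e = cg_energy_forces(x, t, &f);
      gamma *= 1.2; ++accepted;
    } else {
      gamma *= 0.5;
      if (gamma < 1e-14) break;
    }
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = x[3*i+k];
  return List::create(_["coords"] = out, _["energy"] = e,
                      _["accepted_steps"] = accepted);
}

// ---------------------------------------------------------------------------
// Kabsch / quaternion superposition RMSD with analytic gradient
// ---------------------------------------------------------------------------
// Jacobi eigen decomposition for a symmetric 4x4 matrix.
static void jacobi4(double a[4][4], double d[4], double v[4][4]) {
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) v[i][j] = (i == j) ? 1.0 : 0.0;
  for (int sweep = 0; sweep < 100; ++sweep) {
    double off = 0.0;
    for (int p = 0; p < 3; ++p)
      for (int q = p + 1; q < 4; ++q) off += a[p][q] * a[p][q];
    if (off < 1e-24) break;
    for (int p = 0; p < 3; ++p) {
      for (int q = p + 1; q < 4; ++q) {
        if (std::fabs(a[p][q]) < 1e-18) continue;
        double theta = (a[q][q] - a[p][p]) / (2.0 * a[p][q]);
        double tt = (theta >= 0 ? 1.0 : -1.0) /
                    (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(tt * tt + 1.0), s = tt * c;
        for (int k = 0; k < 4; ++k) {
          double akp = a[k][p], akq = a[k][q];
          a[k][p] = c * akp - s * akq;
          a[k][q] = s * akp + c * akq;
        }
        for (int k = 0; k < 4; ++k) {
          double apk = a[p][k], aqk = a[q][k];
          a[p][k] = c * apk - s * aqk;
          a[q][k] = s * apk + c * aqk;
        }
        for (int k = 0; k < 4; ++k) {
          double vkp = v[k][p], vkq = v[k][q];
          v[k][p] = c * vkp - s * vkq;
          v[k][q] = s * vkp + c * vkq;
        }
      }
    }
  }
  for (int i = 0; i < 4; ++i) d[i] = a[i][i];
}

// Optimal-superposition RMSD of mov onto ref (both m x 3 flattened, centered
// internally). If grad != nullptr, fills d(RMSD)/d(mov coords).
static double kabsch_rmsd(const std::vector<double>& mov,
                          const std::vector<double>& ref, int m,
                          std::vector<double>* grad) {
  std::vector<double> xc(3 * m), yc(3 * m);
  double cmx[3] = {0, 0, 0}, cmy[3] = {0, 0, 0};
  for (int i = 0; i < m; ++i)
    for (int k = 0; k < 3; ++k) { cmx[k] += mov[3*i+k]; cmy[k] += ref[3*i+k]; }
  for (int k = 0; k < 3; ++k) { cmx[k] /= m; cmy[k] /= m; }
  double gx = 0.0, gy = 0.0;
  double R[3][3] = {{0,0,0},{0,0,0},{0,0,0}}; // correlation matrix sum y x^T
  for (int i = 0; i < m; ++i) {
    for (int k = 0; k < 3; ++k) {
      xc[3*i+k] = mov[3*i+k] - cmx[k];
      yc[3*i+k] = ref[3*i+k] - cmy[k];
      gx += xc[3*i+k] * xc[3*i+k];
      gy += yc[3*i+k] * yc[3*i+k];
    }
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) R[a][b] += yc[3*i+a] * xc[3*i+b];
  }
  // Horn quaternion matrix
  double K[4][4];
  K[0][0] = R[0][0] + R[1][1] + R[2][2];
  K[0][1] = R[1][2] - R[2][1];
  K[0][2] = R[2][0] - R[0][2];
  K[0][3] = R[0][1] - R[1][0];
  K[1][1] = R[0][0] - R[1][1] - R[2][2];
  K[1][2] = R[0][1] + R[1][0];
  K[1][3] = R[0][2] + R[2][0];
  K[2][2] = -R[0][0] + R[1][1] - R[2][2];
  K[2][3] = R[1][2] + R[2][1];
  K[3][3] = -R[0][0] - R[1][1] + R[2][2];
  for (int i = 1; i < 4; ++i)
    for (int j = 0; j < i; ++j) K[i][j] = K[j][i];
  double d[4], v[4][4];
  jacobi4(K, d, v);
  int imax = 0;
  for (int i = 1; i < 4; ++i) if (d[i] > d[imax]) imax = i;
  double lmax = d[imax];
  double msd = std::max(0.0, (gx + gy - 2.0 * lmax) / m);
  double rmsd = std::sqrt(msd);
  if (grad) {
    // rotation that maps centered ref onto centered mov
    double q0 = v[0][imax], q1 = v[1][imax], q2 = v[2][imax], q3 = v[3][imax];
    double Q[3][3];
    Q[0][0] = q0*q0 + q1*q1 - q2*q2 - q3*q3;
    Q[0][1] = 2.0 * (q1*q2 - q0*q3);
    Q[0][2] = 2.0 * (q1*q3 + q0*q2);
    Q[1][0] = 2.0 * (q1*q2 + q0*q3);
    Q[1][1] = q0*q0 - q1*q1 + q2*q2 - q3*q3;
    Q[1][2] = 2.0 * (q2*q3 - q0*q1);
    Q[2][0] = 2.0 * (q1*q3 - q0*q2);
    Q[2][1] = 2.0 * (q2*q3 + q0*q1);
    Q[2][2] = q0*q0 - q1*q1 - q2*q2 + q3*q3;
    grad->assign(3 * m, 0.0);
    double denom = std::max(rmsd, 1e-12) * m;
    for (int i = 0; i < m; ++i) {
      for (int a = 0; a < 3; ++a) {
        double ry = Q[a][0]*yc[3*i] + Q[a][1]*yc[3*i+1] + Q[a][2]*yc[3*i+2];
        (*grad)[3*i+a] = (xc[3*i+a] - ry) / denom;
      }
    }
  }
  return rmsd;
}

// [[Rcpp::export]]
List cpp_kabsch_rmsd(NumericMatrix mov, NumericMatrix ref, bool gradient = false) {
  int m = mov.nrow();
  std::vector<double> x(3 * m), y(3 * m), g;
  for (int i = 0; i < m; ++i)
    for (int k = 0; k < 3; ++k) { x[3*i+k] = mov(i, k); y[3*i+k] = ref(i, k); }
  double r = kabsch_rmsd(x, y, m, gradient ? &g : nullptr);
  List out = List::create(_["rmsd"] = r);
  if (gradient) {
    NumericMatrix gm(m, 3);
    for (int i = 0; i < m; ++i)
      for (int k = 0; k < 3; ++k) gm(i, k) = g[3*i+k];
    out["gradient"] = gm;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Collective variables
// ---------------------------------------------------------------------------
struct CV {
  int kind;                 // 0 = radius of gyration, 1 = inter-bead distance,
                            // 2 = segment COM distance
  std::vector<int> sel_a, sel_b; // 0-based bead selections
  double gmin, gmax, spacing, width;
  std::vector<double> V, dV;     // bias value and derivative on the grid
  long clamped = 0;
  int ngrid() const { return (int)V.size(); }
};

static double cv_value_grad(const CV& cv, const std::vector<double>& x, int n,
                            std::vector<double>* grad) {
  if (grad) grad->assign(3 * n, 0.0);
  if (cv.kind == 0) {
    const std::vector<int>& sel = cv.sel_a;
    int m = (int)sel.size();
    double cm[3] = {0, 0, 0};
    for (int idx : sel)
      for (int k = 0; k < 3; ++k) cm[k] += x[3*idx+k];
    for (int k = 0; k < 3; ++k) cm[k] /= m;
    double s2 = 0.0;
    for (int idx : sel)
      for (int k = 0; k < 3; ++k) {
        double d = x[3*idx+k] - cm[k]; s2 += d * d;
      }
    double rg = std::sqrt(s2 / m);
    if (grad && rg > 1e-12) {
      for (int idx : sel)
        for (int k = 0; k < 3; ++k)
          (*grad)[3*idx+k] = (x[3*idx+k] - cm[k]) / (m * rg);
    }
    return rg;
  }
  if (cv.kind == 1) {
    int i = cv.sel_a[0], j = cv.sel_b[0];
    double d[3], r2 = 0.0;
    for (int k = 0; k < 3; ++k) { d[k] = x[3*i+k] - x[3*j+k]; r2 += d[k]*d[k]; }
    double r = std::sqrt(std::max(r2, 1e-24));
    if (grad)
      for (int k = 0; k < 3; ++k) {
        (*grad)[3*i+k] = d[k] / r; (*grad)[3*j+k] = -d[k] / r;
      }
    return r;
  }
  // segment COM distance
  double ca[3] = {0,0,0}, cb[3] = {0,0,0};
  int ma = (int)cv.sel_a.size(), mb = (int)cv.sel_b.size();
  for (int idx : cv.sel_a) for (int k = 0; k < 3; ++k) ca[k] += x[3*idx+k];
  for (int idx : cv.sel_b) for (int k = 0; k < 3; ++k) cb[k] += x[3*idx+k];
  double d[3], r2 = 0.0;
  for (int k = 0; k < 3; ++k) {
    ca[k] /= ma; cb[k] /= mb; d[k] = ca[k] - cb[k]; r2 += d[k]*d[k];
  }
  double r = std::sqrt(std::max(r2, 1e-24));
  if (grad)
    for (int k = 0; k < 3; ++k) {
      for (int idx : cv.sel_a) (*grad)[3*idx+k] = d[k] / (r * ma);
      for (int idx : cv.sel_b) (*grad)[3*idx+k] = -d[k] / (r * mb);
    }
  return r;
}

// linear interpolation of bias value and derivative at s (clamped to grid)
static void bias_at(CV& cv, double s, double& v, double& dv) {
  double sc = s;
  if (sc <= cv.gmin) { sc = cv.gmin; if (s < cv.gmin) cv.clamped++; }
  double smax = cv.gmin + (cv.ngrid() - 1) * cv.spacing;
  if (sc >= smax) { sc = smax; if (s > smax) cv.clamped++; }
  double u = (sc - cv.gmin) / cv.spacing;
  int i0 = std::min((int)u, cv.ngrid() - 2);
  double w = u - i0;
  v  = (1.0 - w) * cv.V[i0]  + w * cv.V[i0 + 1];
  dv = (1.0 - w) * cv.dV[i0] + w * cv.dV[i0 + 1];
}

static void add_hill(CV& cv, double s0, double height) {
  int ng = cv.ngrid();
  for (int g = 0; g < ng; ++g) {
    double s = cv.gmin + g * cv.spacing;
    double z = (s - s0) / cv.width;
    if (std::fabs(z) > 8.0) continue;
    double e = height * std::exp(-0.5 * z * z);
    cv.V[g]  += e;
    cv.dV[g] += -z / cv.width * e;
  }
}

// ---------------------------------------------------------------------------
// Metainference helpers
// ---------------------------------------------------------------------------
static inline double sigma_energy_kT(double dev, double sig, double sem,
                                     int sprior) {
  // E(sigma)/kBT for one (replica, datapoint): Gaussian data term +
  // likelihood normalization + prior term (sprior=+1 as printed, -1 Jeffreys)
  double s2 = sig * sig + sem * sem;
  return 0.5 * dev * dev / s2 + sprior * (-std::log(sig)) + 0.5 * std::log(s2);
}

// Standalone Gibbs chain at fixed deviation (for sampler-correctness checks).
// [[Rcpp::export]]
NumericVector cpp_gibbs_chain(double dev, double sigma0, double sem,
                              double lower, double upper, double move_width,
                              int n_sweeps, int sprior, int seed) {
  Rng rng((uint64_t)seed * 2654435761u + 11u);
  NumericVector out(n_sweeps);
  double sig = sigma0;
  for (int t = 0; t < n_sweeps; ++t) {
    double prop = sig + (2.0 * rng.unif() - 1.0) * move_width;
    if (prop >= lower && prop <= upper) {
      double de = sigma_energy_kT(dev, prop, sem, sprior) -
                  sigma_energy_kT(dev, sig, sem, sprior);
      if (de <= 0.0 || rng.unif() < std::exp(-de)) sig = prop;
    }
    out[t] = sig;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Main multi-replica driver
// ---------------------------------------------------------------------------
struct Restraints {
  std::vector<int> ri, rj;        // 0-based bead indices
  std::vector<double> target_A;   // Angstrom
  int nd() const { return (int)ri.size(); }
};

struct Wall {
  std::vector<std::vector<int>> segs;      // bead indices per segment
  std::vector<std::vector<double>> refs;   // centered-at-will reference coords
  double kappa, threshold;
};

// [[Rcpp::export]]
List cpp_run_replicas(List coords_list, Nullable<List> vels_list, List topo,
                      double dt, double friction, double temperature,
                      int n_steps, int save_every, int seed,
                      Nullable<List> restraints_in, Nullable<List> meta_in,
                      Nullable<List> metad_in, Nullable<List> wall_in,
                      Nullable<Function> custom_hook) {
  Topo t = topo_from_list(topo);
  const int n = t.n;
  const int nr = coords_list.size();
  const double kBT = KB * temperature;
  Rng rng((uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL);

  std::vector<std::vector<double>> X(nr, std::vector<double>(3 * n));
  std::vector<std::vector<double>> V(nr, std::vector<double>(3 * n, 0.0));
  for (int r = 0; r < nr; ++r) {
    NumericMatrix cm = coords_list[r];
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) X[r][3*i+k] = cm(i, k);
  }
  if (vels_list.isNotNull()) {
    List vl(vels_list);
    for (int r = 0; r < nr; ++r) {
      NumericMatrix vm = vl[r];
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) V[r][3*i+k] = vm(i, k);
    }
  } else if (temperature > 0) {
    for (int r = 0; r < nr; ++r)
      for (int i = 0; i < n; ++i) {
        double sd = std::sqrt(kBT / t.mass[i]);
        for (int k = 0; k < 3; ++k) V[r][3*i+k] = sd * rng.norm();
      }
  }

  // --- restraints / metainference state
  Restraints rs;
  bool use_mi = false;
  int fwd_mode = 0, sprior = -1, sem_window = 200;
  double sig_lo = 1e-4, sig_hi = 10.0, move_w = 0.1, sem_floor = 0.0;
  double sem_alpha = 1.0;
  std::vector<std::vector<double>> sigB; // [nr][nd] Angstrom
  std::vector<double> sigSEM;            // [nd] Angstrom
  bool gibbs_on = true;
  if (restraints_in.isNotNull()) {
    List rl(restraints_in);
    rs.ri = as<std::vector<int>>(rl["i"]);
    rs.rj = as<std::vector<int>>(rl["j"]);
    rs.target_A = as<std::vector<double>>(rl["target"]);
    use_mi = rs.nd() > 0;
    List ml(meta_in);
    sig_lo = as<double>(ml["sigma_lower"]);
    sig_hi = as<double>(ml["sigma_upper"]);
    move_w = as<double>(ml["move_width"]);
    sem_window = as<int>(ml["sem_window"]);
    fwd_mode = as<int>(ml["forward_mode"]); // 0 = replica average, 1 = per replica
    sprior = as<int>(ml["sigma_prior"]);    // +1 as printed, -1 Jeffreys
    gibbs_on = as<bool>(ml["gibbs"]);
    sem_floor = as<double>(ml["sem_floor"]);
    sem_alpha = as<double>(ml["sem_alpha"]);
    std::vector<double> sig0 = as<std::vector<double>>(ml["sigma_init"]);
    sigB.assign(nr, std::vector<double>(rs.nd()));
    for (int r = 0; r < nr; ++r)
      for (int i = 0; i < rs.nd(); ++i)
        sigB[r][i] = std::min(sig_hi, std::max(sig_lo, sig0[i]));
    sigSEM.assign(rs.nd(), 0.0);
  }
  // SEM accumulators: mean over window of across-replica variance / nr
  std::vector<double> sem_acc(rs.nd(), 0.0);
  int sem_count = 0;

  // --- metadynamics state
  std::vector<CV> cvs;
  bool use_metad = false;
  double hill_h = 0.0, biasf = 10.0;
  int pace = 500;
  std::vector<std::vector<double>> hill_log; // step, replica, s_k..., h_k...
  if (metad_in.isNotNull()) {
    List md(metad_in);
    List cvl = md["cvs"];
    for (int c = 0; c < cvl.size(); ++c) {
      List e = cvl[c];
      CV cv;
      cv.kind = as<int>(e["kind"]);
      cv.sel_a = as<std::vector<int>>(e["sel_a"]);
      cv.sel_b = as<std::vector<int>>(e["sel_b"]);
      cv.gmin = as<double>(e["grid_min"]);
      cv.gmax = as<double>(e["grid_max"]);
      cv.spacing = as<double>(e["grid_spacing"]);
      cv.width = as<double>(e["width"]);
      int ng = (int)std::floor((cv.gmax - cv.gmin) / cv.spacing + 0.5) + 1;
      cv.V.assign(ng, 0.0);
      cv.dV.assign(ng, 0.0);
      cvs.push_back(cv);
    }
    hill_h = as<double>(md["height"]);
    biasf = as<double>(md["bias_factor"]);
    pace = as<int>(md["pace"]);
    use_metad = !cvs.empty() && hill_h > 0.0;
  }
  const int ncv = (int)cvs.size();

  // --- RMSD wall
  Wall wall;
  bool use_wall = false;
  if (wall_in.isNotNull()) {
    List wl(wall_in);
    List segs = wl["segments"];
    List refs = wl["references"];
    for (int s = 0; s < segs.size(); ++s) {
      wall.segs.push_back(as<std::vector<int>>(segs[s]));
      NumericMatrix rm = refs[s];
      std::vector<double> rr(3 * rm.nrow());
      for (int i = 0; i < rm.nrow(); ++i)
        for (int k = 0; k < 3; ++k) rr[3*i+k] = rm(i, k);
      wall.refs.push_back(rr);
    }
    wall.kappa = as<double>(wl["kappa"]);
    wall.threshold = as<double>(wl["threshold"]);
    use_wall = !wall.segs.empty();
  }

  bool has_custom = custom_hook.isNotNull();
  Function hook_fn("identity");
  if (has_custom) hook_fn = Function(custom_hook);

  // --- trajectory storage
  int n_frames = n_steps / std::max(1, save_every) + 1;
  std::vector<NumericVector> traj(nr);
  for (int r = 0; r < nr; ++r) {
    traj[r] = NumericVector((R_xlen_t)n_frames * n * 3);
    traj[r].attr("dim") = IntegerVector::create(n_frames, n, 3);
  }
  NumericMatrix frame_bias(n_frames, nr);
  NumericMatrix frame_epot(n_frames, nr);
  NumericMatrix frame_erestr(n_frames, nr);
  NumericMatrix frame_temp(n_frames, nr);
  std::vector<NumericMatrix> frame_cv;
  for (int c = 0; c < ncv; ++c) frame_cv.push_back(NumericMatrix(n_frames, nr));
  NumericMatrix sem_series(rs.nd() > 0 ? n_frames : 0, rs.nd());

  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));

  // scratch
  std::vector<std::vector<double>> F(nr, std::vector<double>(3 * n, 0.0));
  std::vector<double> epot(nr, 0.0), erestr(nr, 0.0), ebias(nr, 0.0);
  std::vector<std::vector<double>> cv_vals(nr, std::vector<double>(ncv, 0.0));
  std::vector<double> fdist(nr > 0 ? nr * std::max(1, rs.nd()) : 0, 0.0);
  std::vector<double> fmean(std::max(1, rs.nd()), 0.0);
  std::vector<double> cvgrad;

  // compute all force contributions at current coordinates
  auto compute_forces = [&](int step) {
    // distances for restraints
    if (use_mi) {
      for (int r = 0; r < nr; ++r)
        for (int i = 0; i < rs.nd(); ++i) {
          int a = rs.ri[i], b = rs.rj[i];
          double dx = X[r][3*a]-X[r][3*b], dy = X[r][3*a+1]-X[r][3*b+1],
                 dz = X[r][3*a+2]-X[r][3*b+2];
          fdist[r * rs.nd() + i] = 10.0 * std::sqrt(dx*dx+dy*dy+dz*dz); // Angstrom
        }
      for (int i = 0; i < rs.nd(); ++i) {
        double s = 0.0;
        for (int r = 0; r < nr; ++r) s += fdist[r * rs.nd() + i];
        fmean[i] = s / nr;
      }
    }
    for (int r = 0; r < nr; ++r) {
      epot[r] = cg_energy_forces(X[r], t, &F[r]);
      erestr[r] = 0.0;
      ebias[r] = 0.0;
      // metainference data term
      if (use_mi) {
        for (int i = 0; i < rs.nd(); ++i) {
          double sem2 = sigSEM[i] * sigSEM[i];
          if (fwd_mode == 0) {
            double dev = rs.target_A[i] - fmean[i];
            double wsum = 0.0;
            for (int rr2 = 0; rr2 < nr; ++rr2)
              wsum += 1.0 / (sigB[rr2][i] * sigB[rr2][i] + sem2);
            // energy split evenly across replicas for bookkeeping
            erestr[r] += 0.5 * kBT * dev * dev * wsum / nr;
            double pref = kBT * dev * wsum / nr; // dE/d f_r, with df/dX chain below
            int a = rs.ri[i], b = rs.rj[i];
            double dx = X[r][3*a]-X[r][3*b], dy = X[r][3*a+1]-X[r][3*b+1],
                   dz = X[r][3*a+2]-X[r][3*b+2];
            double rnm = std::sqrt(dx*dx+dy*dy+dz*dz);
            if (rnm > 1e-9) {
              double fac = pref * 10.0 / rnm; // dE/dX = -pref * d f/dX; f in A
              F[r][3*a]   += fac * dx; F[r][3*a+1] += fac * dy; F[r][3*a+2] += fac * dz;
              F[r][3*b]   -= fac * dx; F[r][3*b+1] -= fac * dy; F[r][3*b+2] -= fac * dz;
            }
          } else {
            double dev = rs.target_A[i] - fdist[r * rs.nd() + i];
            double w = 1.0 / (sigB[r][i] * sigB[r][i] + sem2);
            erestr[r] += 0.5 * kBT * dev * dev * w;
            double pref = kBT * dev * w;
            int a = rs.ri[i], b = rs.rj[i];
            double dx = X[r][3*a]-X[r][3*b], dy = X[r][3*a+1]-X[r][3*b+1],
                   dz = X[r][3*a+2]-X[r][3*b+2];
            double rnm = std::sqrt(dx*dx+dy*dy+dz*dz);
            if (rnm > 1e-9) {
              double fac = pref * 10.0 / rnm;
              F[r][3*a]   += fac * dx; F[r][3*a+1] += fac * dy; F[r][3*a+2] += fac * dz;
              F[r][3*b]   -= fac * dx; F[r][3*b+1] -= fac * dy; F[r][3*b+2] -= fac * dz;
            }
          }
        }
      }
      // metadynamics bias (shared grids, replica feels bias at own CVs)
      if (use_metad) {
        double expsum = 0.0;
        std::vector<double> vks(ncv), dvks(ncv);
        for (int c = 0; c < ncv; ++c) {
          cv_vals[r][c] = cv_value_grad(cvs[c], X[r], n, nullptr);
          bias_at(cvs[c], cv_vals[r][c], vks[c], dvks[c]);
          expsum += std::exp(-vks[c] / kBT);
        }
        double vpb = -kBT * std::log(expsum / ncv);
        ebias[r] = vpb;
        for (int c = 0; c < ncv; ++c) {
          double pk = std::exp(-vks[c] / kBT) / expsum;
          double dvds = pk * dvks[c];
          if (dvds != 0.0) {
            cv_value_grad(cvs[c], X[r], n, &cvgrad);
            for (int k3 = 0; k3 < 3 * n; ++k3) F[r][k3] -= dvds * cvgrad[k3];
          }
        }
      } else if (ncv > 0) {
        for (int c = 0; c < ncv; ++c)
          cv_vals[r][c] = cv_value_grad(cvs[c], X[r], n, nullptr);
      }
      // RMSD wall
      if (use_wall) {
        for (size_t s = 0; s < wall.segs.size(); ++s) {
          int m = (int)wall.segs[s].size();
          std::vector<double> seg(3 * m), g;
          for (int i = 0; i < m; ++i)
            for (int k = 0; k < 3; ++k) seg[3*i+k] = X[r][3*wall.segs[s][i]+k];
          double rmsd = kabsch_rmsd(seg, wall.refs[s], m, &g);
          if (rmsd > wall.threshold) {
            double over = rmsd - wall.threshold;
            erestr[r] += 0.5 * wall.kappa * over * over;
            for (int i = 0; i < m; ++i)
              for (int k = 0; k < 3; ++k)
                F[r][3*wall.segs[s][i]+k] -= wall.kappa * over * g[3*i+k];
          }
        }
      }
    }
    // custom R hook: list of coords matrices -> list(energy=numeric(nr),
    // forces=list of n x 3 matrices)
    if (has_custom) {
      List cl(nr);
      for (int r = 0; r < nr; ++r) {
        NumericMatrix cm(n, 3);
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < 3; ++k) cm(i, k) = X[r][3*i+k];
        cl[r] = cm;
      }
      List res;
      try {
        res = hook_fn(cl, step);
      } catch (std::exception& e) {
        std::ostringstream msg;
        msg << "hook failed at step " << step << ": " << e.what();
        stop(msg.str());
      }
      NumericVector he = res["energy"];
      List hf = res["forces"];
      for (int r = 0; r < nr; ++r) {
        erestr[r] += he[r];
        NumericMatrix fm = hf[r];
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < 3; ++k) F[r][3*i+k] += fm(i, k);
      }
    }
  };

  auto save_frame = [&](int fidx) {
    for (int r = 0; r < nr; ++r) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          traj[r][(R_xlen_t)fidx + (R_xlen_t)n_frames * (i + (R_xlen_t)n * k)] =
              X[r][3*i+k];
      frame_bias(fidx, r) = ebias[r];
      frame_epot(fidx, r) = epot[r];
      frame_erestr(fidx, r) = erestr[r];
      double ke = 0.0;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          ke += 0.5 * t.mass[i] * V[r][3*i+k] * V[r][3*i+k];
      frame_temp(fidx, r) = 2.0 * ke / (3.0 * n * KB);
      for (int c = 0; c < ncv; ++c) frame_cv[c](fidx, r) = cv_vals[r][c];
    }
    for (int i = 0; i < rs.nd(); ++i)
      if (rs.nd() > 0) sem_series(fidx, i) = sigSEM[i];
  };

  compute_forces(0);
  int fidx = 0;
  save_frame(fidx++);

  for (int step = 1; step <= n_steps; ++step) {
    for (int r = 0; r < nr; ++r) {
      for (int i = 0; i < n; ++i) {
        double invm = 1.0 / t.mass[i];
        for (int k = 0; k < 3; ++k) {
          int ii = 3*i+k;
          V[r][ii] += 0.5 * dt * F[r][ii] * invm;          // B
          X[r][ii] += 0.5 * dt * V[r][ii];                 // A
        }
      }
      for (int i = 0; i < n; ++i) {
        double sd = std::sqrt(kBT / t.mass[i]);
        for (int k = 0; k < 3; ++k) {
          int ii = 3*i+k;
          V[r][ii] = c1 * V[r][ii] + c2 * sd * rng.norm(); // O
          X[r][ii] += 0.5 * dt * V[r][ii];                 // A
        }
      }
    }
    compute_forces(step);
    for (int r = 0; r < nr; ++r)
      for (int i = 0; i < n; ++i) {
        double invm = 1.0 / t.mass[i];
        for (int k = 0; k < 3; ++k)
          V[r][3*i+k] += 0.5 * dt * F[r][3*i+k] * invm;    // B
      }

    if (use_mi) {
      // accumulate across-replica variance of the forward model (SEM)
      if (nr > 1) {
        for (int i = 0; i < rs.nd(); ++i) {
          double ss = 0.0;
          for (int r = 0; r < nr; ++r) {
            double d = fdist[r * rs.nd() + i] - fmean[i];
            ss += d * d;
          }
          sem_acc[i] += ss / (nr - 1) / nr; // var of the replica mean
        }
      }
      sem_count++;
      // seed sigma_SEM from the very first step's across-replica spread so
      // the combined variance never collapses before the first window
      if (step == 1 && nr > 1) {
        for (int i = 0; i < rs.nd(); ++i)
          sigSEM[i] = std::max(std::sqrt(sem_acc[i]), sem_floor);
      }
      if (sem_count >= sem_window) {
        for (int i = 0; i < rs.nd(); ++i) {
          if (nr > 1) {
            // exponential moving average of the window estimate keeps the
            // effective spring constants from jumping at every refresh
            double v = (1.0 - sem_alpha) * sigSEM[i] * sigSEM[i] +
                       sem_alpha * (sem_acc[i] / sem_count);
            sigSEM[i] = std::max(std::sqrt(v), sem_floor);
          } else {
            sigSEM[i] = sem_floor;
          }
          sem_acc[i] = 0.0;
        }
        sem_count = 0;
      }
      // Gibbs sweep over all (replica, datapoint) error parameters
      if (gibbs_on) {
        for (int r = 0; r < nr; ++r)
          for (int i = 0; i < rs.nd(); ++i) {
            double dev = (fwd_mode == 0)
                             ? rs.target_A[i] - fmean[i]
                             : rs.target_A[i] - fdist[r * rs.nd() + i];
            double sig = sigB[r][i];
            double prop = sig + (2.0 * rng.unif() - 1.0) * move_w;
            if (prop >= sig_lo && prop <= sig_hi) {
              double de = sigma_energy_kT(dev, prop, sigSEM[i], sprior) -
                          sigma_energy_kT(dev, sig, sigSEM[i], sprior);
              if (de <= 0.0 || rng.unif() < std::exp(-de)) sigB[r][i] = prop;
            }
          }
      }
    }

    if (use_metad && step % pace == 0) {
      for (int r = 0; r < nr; ++r) {
        double expsum = 0.0;
        std::vector<double> vks(ncv), dvk(ncv);
        for (int c = 0; c < ncv; ++c) {
          double dv;
          bias_at(cvs[c], cv_vals[r][c], vks[c], dv);
          expsum += std::exp(-vks[c] / kBT);
        }
        std::vector<double> row;
        row.push_back(step); row.push_back(r + 1);
        std::vector<double> hs(ncv);
        for (int c = 0; c < ncv; ++c) {
          double pk = std::exp(-vks[c] / kBT) / expsum;
          hs[c] = hill_h * std::exp(-vks[c] / ((biasf - 1.0) * kBT)) * pk;
          row.push_back(cv_vals[r][c]);
        }
        for (int c = 0; c < ncv; ++c) {
          add_hill(cvs[c], cv_vals[r][c], hs[c]);
          row.push_back(hs[c]);
        }
        hill_log.push_back(row);
      }
    }

    if (step % std::max(1, save_every) == 0) save_frame(fidx++);
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  List out;
  List tl(nr), vl(nr);
  for (int r = 0; r < nr; ++r) {
    tl[r] = traj[r];
    NumericMatrix vm(n, 3);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) vm(i, k) = V[r][3*i+k];
    vl[r] = vm;
  }
  out["trajectories"] = tl;
  out["final_velocities"] = vl;
  out["frame_bias"] = frame_bias;
  out["frame_epot"] = frame_epot;
  out["frame_erestraint"] = frame_erestr;
  out["frame_temperature"] = frame_temp;
  List cvl(ncv);
  for (int c = 0; c < ncv; ++c) cvl[c] = frame_cv[c];
  out["frame_cv"] = cvl;
  if (use_mi) {
    NumericMatrix sb(nr, rs.nd());
    for (int r = 0; r < nr; ++r)
      for (int i = 0; i < rs.nd(); ++i) sb(r, i) = sigB[r][i];
    out["sigma_B"] = sb;
    out["sigma_SEM"] = NumericVector(sigSEM.begin(), sigSEM.end());
    out["sigma_SEM_series"] = sem_series;
  }
  if (use_metad) {
    int nh = (int)hill_log.size();
    int ncol = 2 + 2 * ncv;
    NumericMatrix hl(nh, ncol);
    for (int h = 0; h < nh; ++h)
      for (int c = 0; c < ncol; ++c) hl(h, c) = hill_log[h][c];
    out["hills"] = hl;
    List grids(ncv);
    for (int c = 0; c < ncv; ++c) {
      grids[c] = List::create(
          _["grid_min"] = cvs[c].gmin, _["grid_spacing"] = cvs[c].spacing,
          _["V"] = NumericVector(cvs[c].V.begin(), cvs[c].V.end()),
          _["dV"] = NumericVector(cvs[c].dV.begin(), cvs[c].dV.end()),
          _["clamped"] = (double)cvs[c].clamped);
    }
    out["bias_grids"] = grids;
  }
  out["n_frames"] = fidx;
  return out;
}

// ---------------------------------------------------------------------------
// Pairwise distance matrix over frames (for histograms / distograms)
// ---------------------------------------------------------------------------
// frames: list of n x 3 matrices. pairs: 2-column 0-based index matrix.
// Returns nframes x npairs matrix of distances (same units as coords).
// [[Rcpp::export]]
NumericMatrix cpp_pair_distances(List frames, IntegerMatrix pairs) {
  int nf = frames.size(), np = pairs.nrow();
  NumericMatrix out(nf, np);
  for (int f = 0; f < nf; ++f) {
    NumericMatrix c = frames[f];
    for (int p = 0; p < np; ++p) {
      int i = pairs(p, 0), j = pairs(p, 1);
      double dx = c(i,0)-c(j,0), dy = c(i,1)-c(j,1), dz = c(i,2)-c(j,2);
      out(f, p) = std::sqrt(dx*dx + dy*dy + dz*dz);
    }
  }
  return out;
}
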