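// Simulation kernels: Langevin MD and Metropolis MC in reduced units
// (sigma, epsilon, tau; m = 1, kB = 1). Pure computation; all defaults and
// protocol logic live on the R side.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <cstdint>
using namespace Rcpp;

static const double WCA_RMIN2 = std::pow(2.0, 1.0 / 3.0); // (2^{1/6} sigma)^2 for sigma=1

struct PairPot {
  // mode: 0 = cut-shifted LJ, 1 = force-shifted LJ, 2 = WCA
  int mode;
  double eps, sig2, rc, rc2, eshift, fslope;
};

static inline PairPot make_pot(int mode, double eps, double sigma, double rc) {
  PairPot p;
  p.mode = mode; p.eps = eps; p.sig2 = sigma * sigma;
  if (mode == 2) rc = std::pow(2.0, 1.0 / 6.0) * sigma;
  p.rc = rc; p.rc2 = rc * rc;
  double sr6 = std::pow(p.sig2 / (rc * rc), 3.0);
  double ulj = 4.0 * eps * (sr6 * sr6 - sr6);
  double dulj = -24.0 * eps * (2.0 * sr6 * sr6 - sr6) / rc;
  p.eshift = (mode == 2) ? -eps : ulj;    // wca: shift by +eps (stored negated)
  p.fslope = (mode == 1) ? dulj : 0.0;
  return p;
}

// energy and F/r for one pair at squared distance r2 (assumes r2 < rc2)
static inline void pair_ef(const PairPot &p, double r2, double &e, double &f_over_r) {
  double sr6 = p.sig2 / r2; sr6 = sr6 * sr6 * sr6;
  double sr12 = sr6 * sr6;
  if (p.mode == 1) {
    double r = std::sqrt(r2);
    double ulj = 4.0 * p.eps * (sr12 - sr6);
    double dulj = -24.0 * p.eps * (2.0 * sr12 - sr6) / r;
    e = ulj - p.eshift - p.fslope * (r - p.rc);
    f_over_r = (p.fslope - dulj) / r;
  } else {
    e = 4.0 * p.eps * (sr12 - sr6) - p.eshift;
    f_over_r = 24.0 * p.eps * (2.0 * sr12 - sr6) / r2;
  }
}

struct System {
  int N;
  int kind;        // 0 lj_particle, 1 lj_chain, 2 hp_chain, 3 patchy
  int chain_len;
  double L[3];
  std::vector<int> type;        // bead types (0 = H/default, 1 = P)
  PairPot pot[2][2];
  double rmax;                  // largest interaction range
  double k_spring, r0;
  // patchy
  double eps, sigma, cos_ts, lambda;
  std::vector<double> patch;    // 4 x 3 body-frame patch axes (row major)
};

// fast single-shift minimum image; valid for |d| < 1.5 L, i.e. for
// differences of wrapped coordinates (all callers wrap positions first)
static inline void min_image(const System &S, double &dx, double &dy, double &dz) {
  if (dx > 0.5 * S.L[0]) dx -= S.L[0]; else if (dx < -0.5 * S.L[0]) dx += S.L[0];
  if (dy > 0.5 * S.L[1]) dy -= S.L[1]; else if (dy < -0.5 * S.L[1]) dy += S.L[1];
  if (dz > 0.5 * S.L[2]) dz -= S.L[2]; else if (dz < -0.5 * S.L[2]) dz += S.L[2];
}

static inline bool bonded_neighbors(const System &S, int i, int j) {
  if (S.chain_len <= 1) return false;
  if (i / S.chain_len != j / S.chain_len) return false;
  return std::abs(i - j) == 1;
}

static System build_system(NumericMatrix pos, NumericVector Lvec, List model) {
  System S;
  S.N = pos.nrow();
  for (int a = 0; a < 3; ++a) S.L[a] = Lvec[a];
  S.kind = as<int>(model["kind"]);
  S.chain_len = as<int>(model["chain_len"]);
  double eps = as<double>(model["eps"]);
  double sigma = as<double>(model["sigma"]);
  S.eps = eps; S.sigma = sigma;
  S.k_spring = model.containsElementNamed("k_spring") ? as<double>(model["k_spring"]) : 0.0;
  S.r0 = model.containsElementNamed("r0") ? as<double>(model["r0"]) : sigma;
  S.type.assign(S.N, 0);
  if (model.containsElementNamed("types")) {
    IntegerVector t = model["types"];
    if (t.size() == S.N) for (int i = 0; i < S.N; ++i) S.type[i] = t[i];
  }
  double rc = model.containsElementNamed("rc") ? as<double>(model["rc"]) : 3.0 * sigma;
  if (S.kind == 0) {
    S.pot[0][0] = make_pot(0, eps, sigma, rc);
    S.rmax = rc;
  } else if (S.kind == 1) {
    PairPot p = make_pot(1, eps, sigma, rc);
    S.pot[0][0] = S.pot[0][1] = S.pot[1][0] = S.pot[1][1] = p;
    S.rmax = rc;
  } else if (S.kind == 2) {
    S.pot[0][0] = make_pot(1, eps, sigma, rc);            // H-H attractive
    PairPot w = make_pot(2, eps, sigma, 0.0);             // WCA otherwise
    S.pot[0][1] = S.pot[1][0] = S.pot[1][1] = w;
    S.rmax = rc;
  } else { // patchy
    S.cos_ts = as<double>(model["cos_theta_s"]);
    S.lambda = as<double>(model["lambda"]);
    NumericMatrix pd = model["patch_directions"];
    S.patch.resize(12);
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 3; ++b) S.patch[3 * a + b] = pd(a, b);
    S.rmax = sigma + S.lambda;
  }
  return S;
}

// ---------------------------------------------------------------------------
// Neighbor (Verlet) list via cell binning, with O(N^2) fallback in small boxes
// ---------------------------------------------------------------------------
struct NeighborList {
  double rlist, rlist2;
  std::vector<int> nbr;        // flattened neighbor indices (j > i ordering)
  std::vector<int> start;      // start[i]..start[i+1] range into nbr
  std::vector<double> x0;      // positions at build time
};

static void build_nlist(const System &S, const std::vector<double> &x,
                        NeighborList &nl) {
  const int N = S.N;
  nl.start.assign(N + 1, 0);
  nl.nbr.clear();
  nl.x0 = x;
  const double rl2 = nl.rlist2;
  int nc[3];
  for (int a = 0; a < 3; ++a) nc[a] = std::max(1, (int)std::floor(S.L[a] / nl.rlist));
  bool cells_ok = nc[0] >= 3 && nc[1] >= 3 && nc[2] >= 3;
  if (!cells_ok) {
    for (int i = 0; i < N; ++i) {
      nl.start[i] = (int)nl.nbr.size();
      for (int j = i + 1; j < N; ++j) {
        double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1], dz = x[3 * i + 2] - x[3 * j + 2];
        min_image(S, dx, dy, dz);
        if (dx * dx + dy * dy + dz * dz < rl2) nl.nbr.push_back(j);
      }
    }
    nl.start[N] = (int)nl.nbr.size();
    return;
  }
  int ncells = nc[0] * nc[1] * nc[2];
  std::vector<int> head(ncells, -1), nxt(N, -1), cell(N);
  for (int i = 0; i < N; ++i) {
    int ci[3];
    for (int a = 0; a < 3; ++a) {
      double s = x[3 * i + a] / S.L[a];
      s -= std::floor(s);
      ci[a] = std::min(nc[a] - 1, (int)(s * nc[a]));
    }
    int c = (ci[2] * nc[1] + ci[1]) * nc[0] + ci[0];
    cell[i] = c; nxt[i] = head[c]; head[c] = i;
  }
  // precompute the 27 periodic neighbor cells of every cell
  std::vector<int> nbcell(27 * ncells);
  for (int c = 0; c < ncells; ++c) {
    int cx = c % nc[0], cy = (c / nc[0]) % nc[1], cz = c / (nc[0] * nc[1]);
    int k = 0;
    for (int ddz = -1; ddz <= 1; ++ddz)
      for (int ddy = -1; ddy <= 1; ++ddy)
        for (int ddx = -1; ddx <= 1; ++ddx) {
          int ox = (cx + ddx + nc[0]) % nc[0];
          int oy = (cy + ddy + nc[1]) % nc[1];
          int oz = (cz + ddz + nc[2]) % nc[2];
          nbcell[27 * c + k++] = (oz * nc[1] + oy) * nc[0] + ox;
        }
  }
  for (int i = 0; i < N; ++i) {
    nl.start[i] = (int)nl.nbr.size();
    const int c = cell[i];
    const double xi = x[3 * i], yi = x[3 * i + 1], zi = x[3 * i + 2];
    for (int k = 0; k < 27; ++k) {
      for (int j = head[nbcell[27 * c + k]]; j >= 0; j = nxt[j]) {
        if (j <= i) continue;
        double dx = xi - x[3 * j], dy = yi - x[3 * j + 1], dz = zi - x[3 * j + 2];
        min_image(S, dx, dy, dz);
        if (dx * dx + dy * dy + dz * dz < rl2) nl.nbr.push_back(j);
      }
    }
  }
  nl.start[N] = (int)nl.nbr.size();
  // de-duplication unnecessary: with >=3 cells per dim each pair appears once
}

static bool need_rebuild(const System &S, const std::vector<double> &x,
                         const NeighborList &nl, double skin) {
  double lim2 = 0.25 * skin * skin;
  for (int i = 0; i < S.N; ++i) {
    double dx = x[3 * i] - nl.x0[3 * i], dy = x[3 * i + 1] - nl.x0[3 * i + 1],
           dz = x[3 * i + 2] - nl.x0[3 * i + 2];
    min_image(S, dx, dy, dz);
    if (dx * dx + dy * dy + dz * dz > lim2) return true;
  }
  return false;
}

// forces + potential energy (+ diagonal virial when wvir != nullptr)
static double compute_forces(const System &S, const std::vector<double> &x,
                             const NeighborList &nl, std::vector<double> &f,
                             double *wvir) {
  const int N = S.N;
  std::fill(f.begin(), f.end(), 0.0);
  if (wvir) { wvir[0] = wvir[1] = wvir[2] = 0.0; }
  double pe = 0.0;
  for (int i = 0; i < N; ++i) {
    int ti = S.type[i];
    double xi = x[3 * i], yi = x[3 * i + 1], zi = x[3 * i + 2];
    for (int k = nl.start[i]; k < nl.start[i + 1]; ++k) {
      int j = nl.nbr[k];
      if (bonded_neighbors(S, i, j)) continue;
      double dx = xi - x[3 * j], dy = yi - x[3 * j + 1], dz = zi - x[3 * j + 2];
      min_image(S, dx, dy, dz);
      double r2 = dx * dx + dy * dy + dz * dz;
      const PairPot &p = S.pot[ti][S.type[j]];
      if (r2 >= p.rc2) continue;
      double e, fr;
      pair_ef(p, r2, e, fr);
      pe += e;
      double fx = fr * dx, fy = fr * dy, fz = fr * dz;
      f[3 * i] += fx; f[3 * i + 1] += fy; f[3 * i + 2] += fz;
      f[3 * j] -= fx; f[3 * j + 1] -= fy; f[3 * j + 2] -= fz;
      if (wvir) { wvir[0] += dx * fx; wvir[1] += dy * fy; wvir[2] += dz * fz; }
    }
  }
  if (S.chain_len > 1) {
    for (int i = 0; i < N; ++i) {
      if ((i % S.chain_len) == S.chain_len - 1) continue;
      int j = i + 1;
      double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1], dz = x[3 * i + 2] - x[3 * j + 2];
      min_image(S, dx, dy, dz);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      pe += 0.5 * S.k_spring * (r - S.r0) * (r - S.r0);
      double fmag = -S.k_spring * (r - S.r0) / r; // F/r on i
      double fx = fmag * dx, fy = fmag * dy, fz = fmag * dz;
      f[3 * i] += fx; f[3 * i + 1] += fy; f[3 * i + 2] += fz;
      f[3 * j] -= fx; f[3 * j + 1] -= fy; f[3 * j + 2] -= fz;
      if (wvir) { wvir[0] += dx * fx; wvir[1] += dy * fy; wvir[2] += dz * fz; }
    }
  }
  return pe;
}

static void wrap_into_box(const System &S, std::vector<double> &x) {
  for (int i = 0; i < S.N; ++i)
    for (int a = 0; a < 3; ++a) {
      double s = x[3 * i + a] / S.L[a];
      x[3 * i + a] = (s - std::floor(s)) * S.L[a];
    }
}

// [[Rcpp::export]]
List cpp_md_run(NumericMatrix pos, Nullable<NumericMatrix> vel,
                NumericVector Lvec, List model, List params) {
  System S = build_system(pos, Lvec, model);
  const int N = S.N;
  double dt = as<double>(params["dt"]);
  double T = as<double>(params["temperature"]);
  double gamma = as<double>(params["friction"]);
  long n_steps = (long)as<double>(params["n_steps"]);
  int save_interval = as<int>(params["save_interval"]);
  int pressure_interval = as<int>(params["pressure_interval"]);
  uint32_t seed = (uint32_t)as<double>(params["seed"]);
  int cap_steps = as<int>(params["cap_steps"]);
  double cap_disp = as<double>(params["cap_disp"]);
  double skin = as<double>(params["skin"]);
  bool noise = gamma > 0.0;

  for (int a = 0; a < 3; ++a)
    if (S.rmax > 0.5 * S.L[a])
      stop("geometry error: interaction cutoff exceeds half the box length");

  std::vector<double> x(3 * N), v(3 * N), f(3 * N);
  for (int i = 0; i < N; ++i)
    for (int a = 0; a < 3; ++a) x[3 * i + a] = pos(i, a);
  std::mt19937_64 rng(seed ^ 0x9e3779b97f4a7c15ULL);
  std::normal_distribution<double> gauss(0.0, 1.0);
  if (vel.isNotNull()) {
    NumericMatrix vm(vel);
    for (int i = 0; i < N; ++i)
      for (int a = 0; a < 3; ++a) v[3 * i + a] = vm(i, a);
  } else {
    double sd = std::sqrt(T);
    for (int i = 0; i < 3 * N; ++i) v[i] = sd * gauss(rng);
  }

  NeighborList nl;
  nl.rlist = S.rmax + skin; nl.rlist2 = nl.rlist * nl.rlist;
  wrap_into_box(S, x);
  build_nlist(S, x, nl);
  compute_forces(S, x, nl, f, nullptr);

  double c1 = std::exp(-gamma * dt);
  double c2 = noise ? std::sqrt((1.0 - c1 * c1) * T) : 0.0;

  int n_frames_cap = save_interval > 0 ? (int)(n_steps / save_interval) + 1 : 1;
  List traj(0);
  std::vector<double> traj_steps;
  std::vector<double> frame_pe, frame_ke;
  std::vector<double> p_step, p_xx, p_yy, p_zz;
  double V = S.L[0] * S.L[1] * S.L[2];
  (void)n_frames_cap;

  for (long step = 1; step <= n_steps; ++step) {
    bool sample_p = pressure_interval > 0 && (step % pressure_interval == 0);
    // B half
    double half = 0.5 * dt;
    for (int i = 0; i < 3 * N; ++i) v[i] += half * f[i];
    // A half (with early-step displacement cap to relax inserted overlaps)
    if (step <= cap_steps) {
      double vmax = cap_disp / half;
      for (int i = 0; i < N; ++i) {
        double sp = std::sqrt(v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] + v[3 * i + 2] * v[3 * i + 2]);
        if (sp > vmax) { double s = vmax / sp; v[3 * i] *= s; v[3 * i + 1] *= s; v[3 * i + 2] *= s; }
      }
    }
    for (int i = 0; i < 3 * N; ++i) x[i] += half * v[i];
    // O
    if (noise) for (int i = 0; i < 3 * N; ++i) v[i] = c1 * v[i] + c2 * gauss(rng);
    // A half
    for (int i = 0; i < 3 * N; ++i) x[i] += half * v[i];
    // forces (positions kept wrapped so the single-shift minimum image holds)
    wrap_into_box(S, x);
    if (need_rebuild(S, x, nl, skin)) build_nlist(S, x, nl);
    double wvir[3];
    double pe = compute_forces(S, x, nl, f, sample_p ? wvir : nullptr);
    // B half
    for (int i = 0; i < 3 * N; ++i) v[i] += half * f[i];

    if (sample_p) {
      double kxx = 0, kyy = 0, kzz = 0;
      for (int i = 0; i < N; ++i) {
        kxx += v[3 * i] * v[3 * i];
        kyy += v[3 * i + 1] * v[3 * i + 1];
        kzz += v[3 * i + 2] * v[3 * i + 2];
      }
      p_step.push_back((double)step);
      p_xx.push_back((kxx + wvir[0]) / V);
      p_yy.push_back((kyy + wvir[1]) / V);
      p_zz.push_back((kzz + wvir[2]) / V);
    }
    if (save_interval > 0 && (step % save_interval == 0 || step == n_steps)) {
      if (!std::isfinite(x[0]) || !std::isfinite(pe))
        stop("integration error: non-finite coordinates at step %ld", step);
      std::vector<double> xw = x;
      wrap_into_box(S, xw);
      NumericMatrix fr(N, 3);
      for (int i = 0; i < N; ++i)
        for (int a = 0; a < 3; ++a) fr(i, a) = xw[3 * i + a];
      traj.push_back(fr);
      traj_steps.push_back((double)step);
      double ke = 0;
      for (int i = 0; i < 3 * N; ++i) ke += 0.5 * v[i] * v[i];
      frame_pe.push_back(pe);
      frame_ke.push_back(ke);
    }
  }
  for (int i = 0; i < 3 * N; ++i)
    if (!std::isfinite(x[i])) stop("integration error: non-finite coordinates at end of run");
  wrap_into_box(S, x);
  NumericMatrix out_x(N, 3), out_v(N, 3);
  for (int i = 0; i < N; ++i)
    for (int a = 0; a < 3; ++a) { out_x(i, a) = x[3 * i + a]; out_v(i, a) = v[3 * i + a]; }
  int np = (int)p_step.size();
  NumericMatrix pres(np, 4);
  for (int k = 0; k < np; ++k) {
    pres(k, 0) = p_step[k]; pres(k, 1) = p_xx[k]; pres(k, 2) = p_yy[k]; pres(k, 3) = p_zz[k];
  }
  return List::create(_["positions"] = out_x, _["velocities"] = out_v,
                      _["trajectory"] = traj, _["traj_steps"] = wrap(traj_steps),
                      _["frame_pe"] = wrap(frame_pe), _["frame_ke"] = wrap(frame_ke),
                      _["pressure"] = pres);
}

// [[Rcpp::export]]
List cpp_forces_virial(NumericMatrix pos, NumericVector Lvec, List model) {
  System S = build_system(pos, Lvec, model);
  std::vector<double> x(3 * S.N), f(3 * S.N);
  for (int i = 0; i < S.N; ++i)
    for (int a = 0; a < 3; ++a) x[3 * i + a] = pos(i, a);
  wrap_into_box(S, x);
  NeighborList nl;
  nl.rlist = S.rmax; nl.rlist2 = nl.rlist * nl.rlist;
  build_nlist(S, x, nl);
  double wvir[3];
  double pe = compute_forces(S, x, nl, f, wvir);
  NumericMatrix fm(S.N, 3);
  for (int i = 0; i < S.N; ++i)
    for (int a = 0; a < 3; ++a) fm(i, a) = f[3 * i + a];
  return List::create(_["forces"] = fm, _["energy"] = pe,
                      _["virial"] = NumericVector::create(wvir[0], wvir[1], wvir[2]));
}

// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix pos, NumericVector Lvec, double r_cut) {
  List model = List::create(_["kind"] = 0, _["chain_len"] = 1,
                            _["eps"] = 1.0, _["sigma"] = 1.0, _["rc"] = r_cut);
  System S = build_system(pos, Lvec, model);
  for (int a = 0; a < 3; ++a)
    if (r_cut > 0.5 * S.L[a]) stop("geometry error: r_cut exceeds half the box length");
  std::vector<double> x(3 * S.N);
  for (int i = 0; i < S.N; ++i)
    for (int a = 0; a < 3; ++a) x[3 * i + a] = pos(i, a);
  wrap_into_box(S, x);
  NeighborList nl;
  nl.rlist = r_cut; nl.rlist2 = r_cut * r_cut;
  build_nlist(S, x, nl);
  std::vector<int> ii, jj;
  for (int i = 0; i < S.N; ++i)
    for (int k = nl.start[i]; k < nl.start[i + 1]; ++k) { ii.push_back(i + 1); jj.push_back(nl.nbr[k] + 1); }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) { out(k, 0) = ii[k]; out(k, 1) = jj[k]; }
  return out;
}

// ---------------------------------------------------------------------------
// Patchy / MC machinery
// ---------------------------------------------------------------------------

// body->lab: orientation stored row-major, rows = body axes in lab frame
static inline void body_to_lab(const double *o, const double *vb, double *vl) {
  vl[0] = vb[0] * o[0] + vb[1] * o[3] + vb[2] * o[6];
  vl[1] = vb[0] * o[1] + vb[1] * o[4] + vb[2] * o[7];
  vl[2] = vb[0] * o[2] + vb[1] * o[5] + vb[2] * o[8];
}

// patchy pair energy; returns +inf flag via overlap
static inline double patchy_pair(const System &S, const double *xi, const double *oi,
                                 const double *xj, const double *oj, bool &overlap) {
  double dx = xj[0] - xi[0], dy = xj[1] - xi[1], dz = xj[2] - xi[2];
  double d[3] = {dx, dy, dz};
  min_image(S, d[0], d[1], d[2]);
  double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
  double sig2 = S.sigma * S.sigma;
  overlap = false;
  if (r2 < sig2) { overlap = true; return 0.0; }
  double rout = S.sigma + S.lambda;
  if (r2 >= rout * rout) return 0.0;
  double r = std::sqrt(r2);
  double rh[3] = {d[0] / r, d[1] / r, d[2] / r};
  int k1 = 0, k2 = 0;
  double nl_[3];
  for (int a = 0; a < 4; ++a) {
    body_to_lab(oi, &S.patch[3 * a], nl_);
    if (nl_[0] * rh[0] + nl_[1] * rh[1] + nl_[2] * rh[2] > S.cos_ts) ++k1;
  }
  if (k1 == 0) return 0.0;
  for (int b = 0; b < 4; ++b) {
    body_to_lab(oj, &S.patch[3 * b], nl_);
    if (-(nl_[0] * rh[0] + nl_[1] * rh[1] + nl_[2] * rh[2]) > S.cos_ts) ++k2;
  }
  return -S.eps * (double)(k1 * k2);
}

struct CellGrid {
  int nc[3], ncells;
  double inv[3];
  std::vector<int> head, nxt, prev, cell;
  void init(const System &S, double range, int N) {
    for (int a = 0; a < 3; ++a) {
      nc[a] = std::max(1, (int)std::floor(S.L[a] / range));
      inv[a] = nc[a] / S.L[a];
    }
    ncells = nc[0] * nc[1] * nc[2];
    head.assign(ncells, -1); nxt.assign(N, -1); prev.assign(N, -1); cell.assign(N, -1);
  }
  inline int cell_of(const System &S, const double *x) const {
    int ci[3];
    for (int a = 0; a < 3; ++a) {
      double s = x[a] / S.L[a]; s -= std::floor(s);
      ci[a] = std::min(nc[a] - 1, (int)(s * S.L[a] * inv[a]));
    }
    return (ci[2] * nc[1] + ci[1]) * nc[0] + ci[0];
  }
  void insert(int i, int c) {
    cell[i] = c; prev[i] = -1; nxt[i] = head[c];
    if (head[c] >= 0) prev[head[c]] = i;
    head[c] = i;
  }
  void remove(int i) {
    int c = cell[i];
    if (prev[i] >= 0) nxt[prev[i]] = nxt[i]; else head[c] = nxt[i];
    if (nxt[i] >= 0) prev[nxt[i]] = prev[i];
    cell[i] = -1;
  }
  bool small() const { return nc[0] < 3 || nc[1] < 3 || nc[2] < 3; }
};

// energy of particle i against all others (cell-assisted; brute in small boxes)
static double one_particle_energy(const System &S, const std::vector<double> &x,
                                  const std::vector<double> &ori, int i,
                                  const double *xi, const double *oi,
                                  const CellGrid &cg, bool use_cells, bool &overlap) {
  overlap = false;
  double e = 0.0;
  const bool patchy = S.kind == 3;
  const PairPot &p = S.pot[0][0];
  auto eval = [&](int j) {
    if (j == i) return;
    if (patchy) {
      bool ov;
      e += patchy_pair(S, xi, oi, &x[3 * j], &ori[9 * j], ov);
      if (ov) overlap = true;
    } else {
      double dx = xi[0] - x[3 * j], dy = xi[1] - x[3 * j + 1], dz = xi[2] - x[3 * j + 2];
      min_image(S, dx, dy, dz);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < p.rc2) {
        double ee, fr;
        pair_ef(p, r2, ee, fr);
        e += ee;
      }
    }
  };
  if (!use_cells) {
    for (int j = 0; j < S.N; ++j) { eval(j); if (overlap) return 0.0; }
    return e;
  }
  int c = cg.cell_of(S, xi);
  int cx = c % cg.nc[0], cy = (c / cg.nc[0]) % cg.nc[1], cz = c / (cg.nc[0] * cg.nc[1]);
  for (int ddz = -1; ddz <= 1; ++ddz)
    for (int ddy = -1; ddy <= 1; ++ddy)
      for (int ddx = -1; ddx <= 1; ++ddx) {
        int ox = (cx + ddx + cg.nc[0]) % cg.nc[0];
        int oy = (cy + ddy + cg.nc[1]) % cg.nc[1];
        int oz = (cz + ddz + cg.nc[2]) % cg.nc[2];
        int oc = (oz * cg.nc[1] + oy) * cg.nc[0] + ox;
        for (int j = cg.head[oc]; j >= 0; j = cg.nxt[j]) {
          eval(j);
          if (overlap) return 0.0;
        }
      }
  return e;
}

// rotate vector v in place about unit axis n by angle a (Rodrigues)
static inline void rodrigues(double *v, const double *n, double a) {
  double c = std::cos(a), s = std::sin(a);
  double nv = n[0] * v[0] + n[1] * v[1] + n[2] * v[2];
  double cx = n[1] * v[2] - n[2] * v[1];
  double cy = n[2] * v[0] - n[0] * v[2];
  double cz = n[0] * v[1] - n[1] * v[0];
  double r0 = v[0] * c + cx * s + n[0] * nv * (1 - c);
  double r1 = v[1] * c + cy * s + n[1] * nv * (1 - c);
  double r2 = v[2] * c + cz * s + n[2] * nv * (1 - c);
  v[0] = r0; v[1] = r1; v[2] = r2;
}

// symmetric small-rotation proposal: tilt z within a cap, spin about new z
static void propose_rotation(double *o, double halfwidth, std::mt19937_64 &rng,
                             std::uniform_real_distribution<double> &unif) {
  double zax[3] = {o[6], o[7], o[8]};
  double xax[3] = {o[0], o[1], o[2]};
  double yax[3] = {o[3], o[4], o[5]};
  double cosmax = std::cos(halfwidth);
  double cphi = 1.0 - unif(rng) * (1.0 - cosmax);   // uniform over the cap
  double phi = std::acos(std::min(1.0, cphi));
  double psi = 2.0 * M_PI * unif(rng);
  double newz[3];
  for (int a = 0; a < 3; ++a)
    newz[a] = cphi * zax[a] + std::sin(phi) * (std::cos(psi) * xax[a] + std::sin(psi) * yax[a]);
  // line of nodes: old z x new z
  double n[3] = {zax[1] * newz[2] - zax[2] * newz[1],
                 zax[2] * newz[0] - zax[0] * newz[2],
                 zax[0] * newz[1] - zax[1] * newz[0]};
  double nn = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
  if (nn > 1e-14) {
    for (int a = 0; a < 3; ++a) n[a] /= nn;
    rodrigues(&o[0], n, phi);
    rodrigues(&o[3], n, phi);
    rodrigues(&o[6], n, phi);
  }
  double alpha = (2.0 * unif(rng) - 1.0) * halfwidth;
  double nz[3] = {o[6], o[7], o[8]};
  rodrigues(&o[0], nz, alpha);
  rodrigues(&o[3], nz, alpha);
}

static void orthonormalize(double *o) {
  // Gram-Schmidt on rows, z = x cross y to keep a proper rotation
  double nx = std::sqrt(o[0] * o[0] + o[1] * o[1] + o[2] * o[2]);
  for (int a = 0; a < 3; ++a) o[a] /= nx;
  double d = o[0] * o[3] + o[1] * o[4] + o[2] * o[5];
  for (int a = 0; a < 3; ++a) o[3 + a] -= d * o[a];
  double ny = std::sqrt(o[3] * o[3] + o[4] * o[4] + o[5] * o[5]);
  for (int a = 0; a < 3; ++a) o[3 + a] /= ny;
  o[6] = o[1] * o[5] - o[2] * o[4];
  o[7] = o[2] * o[3] - o[0] * o[5];
  o[8] = o[0] * o[4] - o[1] * o[3];
}

// [[Rcpp::export]]
List cpp_mc_run(NumericMatrix pos, Nullable<NumericMatrix> orient,
                NumericVector Lvec, List model, List params) {
  System S = build_system(pos, Lvec, model);
  const int N = S.N;
  long n_sweeps = (long)as<double>(params["n_steps"]);
  double T = as<double>(params["temperature"]);
  double dhw = as<double>(params["displacement_halfwidth"]);
  double rhw = as<double>(params["rotation_angle_halfwidth"]);
  int save_interval = as<int>(params["save_interval"]);
  bool rotations = as<bool>(params["rotations"]);
  uint32_t seed = (uint32_t)as<double>(params["seed"]);
  const bool patchy = S.kind == 3;

  std::vector<double> x(3 * N), ori;
  for (int i = 0; i < N; ++i)
    for (int a = 0; a < 3; ++a) x[3 * i + a] = pos(i, a);
  if (patchy) {
    if (orient.isNull()) stop("patchy MC requires orientations");
    NumericMatrix om(orient);
    ori.resize(9 * N);
    for (int i = 0; i < N; ++i)
      for (int a = 0; a < 9; ++a) ori[9 * i + a] = om(i, a);
  }
  wrap_into_box(S, x);

  double range = S.rmax;
  CellGrid cg;
  cg.init(S, range, N);
  bool use_cells = !cg.small();
  if (use_cells)
    for (int i = 0; i < N; ++i) cg.insert(i, cg.cell_of(S, &x[3 * i]));

  std::mt19937_64 rng(seed ^ 0x2545f4914f6cdd1dULL);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // initial total energy (half sum of per-particle energies)
  double etot = 0.0;
  {
    bool ov;
    for (int i = 0; i < N; ++i)
      etot += one_particle_energy(S, x, ori, i, &x[3 * i], patchy ? &ori[9 * i] : nullptr,
                                  cg, use_cells, ov);
    etot *= 0.5;
  }

  long acc_disp = 0, try_disp = 0, acc_rot = 0, try_rot = 0;
  List traj(0), traj_orient(0);
  std::vector<double> traj_steps, e_series;

  for (long sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int i = 0; i < N; ++i) {
      bool do_rot = rotations && unif(rng) < 0.5;
      bool ov;
      double e_old = one_particle_energy(S, x, ori, i, &x[3 * i],
                                         patchy ? &ori[9 * i] : nullptr, cg, use_cells, ov);
      if (do_rot) {
        ++try_rot;
        double onew[9];
        for (int a = 0; a < 9; ++a) onew[a] = ori[9 * i + a];
        propose_rotation(onew, rhw, rng, unif);
        double e_new = one_particle_energy(S, x, ori, i, &x[3 * i], onew, cg, use_cells, ov);
        if (!ov) {
          double dE = e_new - e_old;
          if (dE <= 0.0 || unif(rng) < std::exp(-dE / T)) {
            for (int a = 0; a < 9; ++a) ori[9 * i + a] = onew[a];
            etot += dE;
            ++acc_rot;
          }
        }
      } else {
        ++try_disp;
        double xnew[3];
        for (int a = 0; a < 3; ++a) xnew[a] = x[3 * i + a] + (2.0 * unif(rng) - 1.0) * dhw;
        double e_new = one_particle_energy(S, x, ori, i, xnew,
                                           patchy ? &ori[9 * i] : nullptr, cg, use_cells, ov);
        if (!ov) {
          double dE = e_new - e_old;
          if (dE <= 0.0 || unif(rng) < std::exp(-dE / T)) {
            if (use_cells) {
              int cnew = cg.cell_of(S, xnew);
              if (cnew != cg.cell[i]) { cg.remove(i); cg.insert(i, cnew); }
            }
            for (int a = 0; a < 3; ++a) {
              double s = xnew[a] / S.L[a];
              x[3 * i + a] = (s - std::floor(s)) * S.L[a];
            }
            etot += dE;
            ++acc_disp;
          }
        }
      }
    }
    if (patchy && sweep % 1000 == 0)
      for (int i = 0; i < N; ++i) orthonormalize(&ori[9 * i]);
    if (save_interval > 0 && (sweep % save_interval == 0 || sweep == n_sweeps)) {
      NumericMatrix fr(N, 3);
      for (int i = 0; i < N; ++i)
        for (int a = 0; a < 3; ++a) fr(i, a) = x[3 * i + a];
      traj.push_back(fr);
      if (patchy) {
        NumericMatrix orfr(N, 9);
        for (int i = 0; i < N; ++i)
          for (int a = 0; a < 9; ++a) orfr(i, a) = ori[9 * i + a];
        traj_orient.push_back(orfr);
      }
      traj_steps.push_back((double)sweep);
      e_series.push_back(etot);
    }
  }

  NumericMatrix out_x(N, 3);
  for (int i = 0; i < N; ++i)
    for (int a = 0; a < 3; ++a) out_x(i, a) = x[3 * i + a];
  NumericMatrix out_o(patchy ? N : 0, 9);
  if (patchy)
    for (int i = 0; i < N; ++i)
      for (int a = 0; a < 9; ++a) out_o(i, a) = ori[9 * i + a];
  // independent full recomputation for bookkeeping checks
  double e_recomputed = 0.0;
  {
    bool ov;
    for (int i = 0; i < N; ++i)
      e_recomputed += one_particle_energy(S, x, ori, i, &x[3 * i],
                                          patchy ? &ori[9 * i] : nullptr, cg, use_cells, ov);
    e_recomputed *= 0.5;
  }
  return List::create(_["positions"] = out_x, _["orientations"] = out_o,
                      _["trajectory"] = traj, _["traj_orientations"] = traj_orient,
                      _["traj_steps"] = wrap(traj_steps), _["energy_series"] = wrap(e_series),
                      _["energy"] = etot, _["energy_recomputed"] = e_recomputed,
                      _["acc_disp"] = (double)acc_disp, _["try_disp"] = (double)try_disp,
                      _["acc_rot"] = (double)acc_rot, _["try_rot"] = (double)try_rot);
}

// [[Rcpp::export]]
double cpp_total_energy(NumericMatrix pos, Nullable<NumericMatrix> orient,
                        NumericVector Lvec, List model) {
  System S = build_system(pos, Lvec, model);
  const int N = S.N;
  std::vector<double> x(3 * N), ori;
  for (int i = 0; i < N; ++i)
    for (int a = 0; a < 3; ++a) x[3 * i + a] = pos(i, a);
  const bool patchy = S.kind == 3;
  if (patchy) {
    NumericMatrix om(orient);
    ori.resize(9 * N);
    for (int i = 0; i < N; ++i)
      for (int a = 0; a < 9; ++a) ori[9 * i + a] = om(i, a);
  }
  wrap_into_box(S, x);
  double e = 0.0;
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      if (patchy) {
        bool ov;
        double ee = patchy_pair(S, &x[3 * i], &ori[9 * i], &x[3 * j], &ori[9 * j], ov);
        if (ov) return R_PosInf;
        e += ee;
      } else {
        if (bonded_neighbors(S, i, j)) continue;
        double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1], dz = x[3 * i + 2] - x[3 * j + 2];
        min_image(S, dx, dy, dz);
        double r2 = dx * dx + dy * dy + dz * dz;
        const PairPot &p = S.pot[S.type[i]][S.type[j]];
        if (r2 < p.rc2) {
          double ee, fr;
          pair_ef(p, r2, ee, fr);
          e += ee;
        }
      }
    }
  }
  if (S.chain_len > 1)
    for (int i = 0; i < N; ++i) {
      if ((i % S.chain_len) == S.chain_len - 1) continue;
      double dx = x[3 * i] - x[3 * (i + 1)], dy = x[3 * i + 1] - x[3 * (i + 1) + 1],
             dz = x[3 * i + 2] - x[3 * (i + 1) + 2];
      min_image(S, dx, dy, dz);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      e += 0.5 * S.k_spring * (r - S.r0) * (r - S.r0);
    }
  return e;
}

// [[Rcpp::export]]
List cpp_rotate_sample(NumericMatrix o0, double halfwidth, int n_moves, int seed) {
  double o[9];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) o[3 * r + c] = o0(r, c);
  std::mt19937_64 rng((uint32_t)seed ^ 0x853c49e6748fea9bULL);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  NumericMatrix zaxes(n_moves, 3);
  for (int k = 0; k < n_moves; ++k) {
    propose_rotation(o, halfwidth, rng, unif);
    if ((k + 1) % 1000 == 0) orthonormalize(o);
    zaxes(k, 0) = o[6]; zaxes(k, 1) = o[7]; zaxes(k, 2) = o[8];
  }
  NumericMatrix out(3, 3);
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) out(r, c) = o[3 * r + c];
  return List::create(_["orientation"] = out, _["z_axes"] = zaxes);
}

// [[Rcpp::export]]
NumericVector cpp_field_density(NumericMatrix pos, NumericVector Lvec,
                                IntegerVector ncells, double radius) {
  int N = pos.nrow();
  double L[3] = {Lvec[0], Lvec[1], Lvec[2]};
  int nc[3] = {ncells[0], ncells[1], ncells[2]};
  int M = nc[0] * nc[1] * nc[2];
  NumericVector out(M);
  double r2 = radius * radius;
  double vol = 4.0 / 3.0 * M_PI * radius * radius * radius;
  std::vector<double> x(3 * N);
  for (int i = 0; i < N; ++i)
    for (int a = 0; a < 3; ++a) {
      double s = pos(i, a) / L[a];
      x[3 * i + a] = (s - std::floor(s)) * L[a];
    }
  for (int k = 0; k < M; ++k) {
    int kx = k % nc[0], ky = (k / nc[0]) % nc[1], kz = k / (nc[0] * nc[1]);
    double c[3] = {(kx + 0.5) * L[0] / nc[0], (ky + 0.5) * L[1] / nc[1],
                   (kz + 0.5) * L[2] / nc[2]};
    int cnt = 0;
    for (int i = 0; i < N; ++i) {
      double dx = x[3 * i] - c[0], dy = x[3 * i + 1] - c[1], dz = x[3 * i + 2] - c[2];
      if (dx > 0.5 * L[0]) dx -= L[0]; else if (dx < -0.5 * L[0]) dx += L[0];
      if (dy > 0.5 * L[1]) dy -= L[1]; else if (dy < -0.5 * L[1]) dy += L[1];
      if (dz > 0.5 * L[2]) dz -= L[2]; else if (dz < -0.5 * L[2]) dz += L[2];
      if (dx * dx + dy * dy + dz * dz < r2) ++cnt;
    }
    out[k] = cnt / vol;
  }
  out.attr("dim") = IntegerVector::create(nc[0], nc[1], nc[2]);
  return out;
}
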