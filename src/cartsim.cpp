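// Core numerical kernels and the simulation engine.
//
// All stochastic draws go through R's RNG (unif_rand/norm_rand) so that a
// single set.seed() on the R side makes every run bitwise reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// Voxel grid helpers (cubic voxels, origin at the domain corner, half-open
// intervals: position x belongs to voxel floor(x/dx), 0-based).
// ---------------------------------------------------------------------------

struct GridDims {
  int nx, ny, nz;
  double dx;
  int n() const { return nx * ny * nz; }
  int idx(int i, int j, int k) const { return i + nx * (j + ny * k); }
  int clampi(int i, int n_) const { return i < 0 ? 0 : (i >= n_ ? n_ - 1 : i); }
  int voxel_of(double x, double y, double z) const {
    int i = clampi((int)std::floor(x / dx), nx);
    int j = clampi((int)std::floor(y / dx), ny);
    int k = clampi((int)std::floor(z / dx), nz);
    return idx(i, j, k);
  }
  bool in_domain(double x, double y, double z) const {
    return x >= 0 && y >= 0 && z >= 0 &&
           x < nx * dx && y < ny * dx && z < nz * dx;
  }
};

// Locally-one-dimensional (LOD) implicit diffusion: one tridiagonal solve per
// grid line per axis, with zero-flux (Neumann) ends.  Decay is applied as a
// separate implicit scalar step, so D = 0 reduces exactly to
// c <- c / (1 + lambda * dt).
struct ThomasAxis {
  // Precomputed forward-elimination coefficients for the constant tridiagonal
  // matrix (I - theta * L1d) with Neumann boundaries.
  std::vector<double> cp;        // modified super-diagonal
  std::vector<double> inv_den;   // 1 / (diag - sub * cp[i-1])
  double theta;
  void init(int n, double theta_) {
    theta = theta_;
    cp.assign(n, 0.0);
    inv_den.assign(n, 0.0);
    double sub = -theta, sup = -theta;
    std::vector<double> diag(n, 1.0 + 2.0 * theta);
    if (n >= 1) { diag[0] = 1.0 + theta; diag[n - 1] = 1.0 + theta; }
    if (n == 1) { diag[0] = 1.0; }
    cp[0] = sup / diag[0];
    inv_den[0] = 1.0 / diag[0];
    for (int i = 1; i < n; ++i) {
      double den = diag[i] - sub * cp[i - 1];
      inv_den[i] = 1.0 / den;
      cp[i] = sup / den;
    }
  }
  // Solve in place along a strided line.
  void solve(double* v, int n, int stride) const {
    if (n == 1) return;
    double sub = -theta;
    v[0] = v[0] * inv_den[0];
    for (int i = 1; i < n; ++i)
      v[i * stride] = (v[i * stride] - sub * v[(i - 1) * stride]) * inv_den[i];
    for (int i = n - 2; i >= 0; --i)
      v[i * stride] -= cp[i] * v[(i + 1) * stride];
  }
};

static void lod_diffusion_step_cached(double* c, const GridDims& g, double D,
                                      double lambda, double dt,
                                      const ThomasAxis& tx,
                                      const ThomasAxis& ty,
                                      const ThomasAxis& tz) {
  const int n = g.n();
  // implicit decay
  if (lambda > 0) {
    double f = 1.0 / (1.0 + lambda * dt);
    for (int i = 0; i < n; ++i) c[i] *= f;
  }
  if (D <= 0) return;
  // x sweeps
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      tx.solve(c + g.idx(0, j, k), g.nx, 1);
  // y sweeps
  for (int k = 0; k < g.nz; ++k)
    for (int i = 0; i < g.nx; ++i)
      ty.solve(c + g.idx(i, 0, k), g.ny, g.nx);
  // z sweeps
  for (int j = 0; j < g.ny; ++j)
    for (int i = 0; i < g.nx; ++i)
      tz.solve(c + g.idx(i, j, 0), g.nz, g.nx * g.ny);
}

static void lod_diffusion_step(double* c, const GridDims& g, double D,
                               double lambda, double dt) {
  ThomasAxis tx, ty, tz;
  double theta = D * dt / (g.dx * g.dx);
  tx.init(g.nx, theta);
  ty.init(g.ny, theta);
  tz.init(g.nz, theta);
  lod_diffusion_step_cached(c, g, D, lambda, dt, tx, ty, tz);
}

// Rate-limited implicit secretion/uptake on a single voxel.
// rho = cell volume / voxel volume.  Secretion pushes the voxel toward the
// substrate's saturation value, uptake is a proportional sink; both are
// unconditionally positivity-preserving.
static inline void exchange_voxel(double& c, double secretion, double uptake,
                                  double saturation, double rho, double dt) {
  double a_s = dt * rho * secretion;
  double a_u = dt * rho * uptake;
  if (a_s == 0 && a_u == 0) return;
  c = (c + a_s * saturation) / (1.0 + a_s + a_u);
}

static inline void gradient_at(const double* c, const GridDims& g,
                               double x, double y, double z, double out[3]) {
  int i = g.clampi((int)std::floor(x / g.dx), g.nx);
  int j = g.clampi((int)std::floor(y / g.dx), g.ny);
  int k = g.clampi((int)std::floor(z / g.dx), g.nz);
  // central differences on voxel centres, one-sided at domain faces
  int il = i > 0 ? i - 1 : i, ir = i < g.nx - 1 ? i + 1 : i;
  int jl = j > 0 ? j - 1 : j, jr = j < g.ny - 1 ? j + 1 : j;
  int kl = k > 0 ? k - 1 : k, kr = k < g.nz - 1 ? k + 1 : k;
  out[0] = (ir == il) ? 0.0 : (c[g.idx(ir, j, k)] - c[g.idx(il, j, k)]) / ((ir - il) * g.dx);
  out[1] = (jr == jl) ? 0.0 : (c[g.idx(i, jr, k)] - c[g.idx(i, jl, k)]) / ((jr - jl) * g.dx);
  out[2] = (kr == kl) ? 0.0 : (c[g.idx(i, j, kr)] - c[g.idx(i, j, kl)]) / ((kr - kl) * g.dx);
}

// ---------------------------------------------------------------------------
// Exported microenvironment kernels (module surface; also used by the engine)
// ---------------------------------------------------------------------------

static GridDims dims_from(IntegerVector dims, double dx) {
  GridDims g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2]; g.dx = dx;
  return g;
}

// [[Rcpp::export]]
NumericVector cpp_lod_step(NumericVector conc, IntegerVector dims, double dx,
                           double D, double lambda, double dt,
                           IntegerVector dirichlet_idx,
                           NumericVector dirichlet_val) {
  GridDims g = dims_from(dims, dx);
  NumericVector out = clone(conc);
  lod_diffusion_step(REAL(out), g, D, lambda, dt);
  for (int q = 0; q < dirichlet_idx.size(); ++q)
    out[dirichlet_idx[q]] = dirichlet_val[q];
  for (int i = 0; i < out.size(); ++i) {
    if (!R_finite(out[i]))
      stop("non-finite concentration at voxel %d after diffusion step", i + 1);
    if (out[i] < 0) out[i] = 0;  // guard FP undershoot
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_apply_exchange(NumericVector conc, IntegerVector dims,
                                 double dx, NumericMatrix pos,
                                 NumericVector secretion, NumericVector uptake,
                                 double saturation, NumericVector cell_volume,
                                 double dt) {
  GridDims g = dims_from(dims, dx);
  NumericVector out = clone(conc);
  double vvox = dx * dx * dx;
  for (int a = 0; a < pos.nrow(); ++a) {
    if (!g.in_domain(pos(a, 0), pos(a, 1), pos(a, 2)))
      stop("agent %d at (%g, %g, %g) lies outside the domain", a + 1,
           pos(a, 0), pos(a, 1), pos(a, 2));
    int v = g.voxel_of(pos(a, 0), pos(a, 1), pos(a, 2));
    exchange_voxel(out[v], secretion[a], uptake[a], saturation,
                   cell_volume[a] / vvox, dt);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_field(NumericVector conc, IntegerVector dims,
                               double dx, NumericMatrix pos) {
  GridDims g = dims_from(dims, dx);
  NumericVector out(pos.nrow());
  for (int a = 0; a < pos.nrow(); ++a) {
    if (!g.in_domain(pos(a, 0), pos(a, 1), pos(a, 2)))
      stop("position (%g, %g, %g) lies outside the domain",
           pos(a, 0), pos(a, 1), pos(a, 2));
    out[a] = conc[g.voxel_of(pos(a, 0), pos(a, 1), pos(a, 2))];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_gradient(NumericVector conc, IntegerVector dims,
                                  double dx, NumericMatrix pos) {
  GridDims g = dims_from(dims, dx);
  NumericMatrix out(pos.nrow(), 3);
  double grad[3];
  for (int a = 0; a < pos.nrow(); ++a) {
    if (!g.in_domain(pos(a, 0), pos(a, 1), pos(a, 2)))
      stop("position (%g, %g, %g) lies outside the domain",
           pos(a, 0), pos(a, 1), pos(a, 2));
    gradient_at(REAL(conc), g, pos(a, 0), pos(a, 1), pos(a, 2), grad);
    out(a, 0) = grad[0]; out(a, 1) = grad[1]; out(a, 2) = grad[2];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Mechanics: pairwise adhesion-repulsion velocities and a voxelised
// neighbour list.
// ---------------------------------------------------------------------------

// Velocity contribution on agent a from agent b.
// Repulsion C*(1 - d/(Ra+Rb))^2 for d < Ra+Rb (C = sqrt(Ca*Cb) across types);
// adhesion C_cca*(1 - d/R_Apair)^2 in the ring Ra+Rb <= d < R_Apair with
// R_Apair = adh_scale*(Ra+Rb).  Forces are expressed directly as velocities
// (unit drag absorbed into the constants).
static inline bool pair_velocity(double ax, double ay, double az,
                                 double bx, double by, double bz,
                                 double Ra, double Rb,
                                 double ccr_a, double ccr_b, double cca,
                                 double adh_scale, double out[3],
                                 int* coincident_count) {
  double ux = ax - bx, uy = ay - by, uz = az - bz;
  double d2 = ux * ux + uy * uy + uz * uz;
  double Rsum = Ra + Rb;
  double Rmax = adh_scale * Rsum;
  out[0] = out[1] = out[2] = 0.0;
  if (d2 >= Rmax * Rmax) return false;
  double d = std::sqrt(d2);
  if (d < 1e-9) {
    // coincident centres: deterministic-under-seed random repulsion axis
    if (coincident_count) ++(*coincident_count);
    double th = 2.0 * M_PI * unif_rand();
    double cz = 2.0 * unif_rand() - 1.0;
    double sz = std::sqrt(std::max(0.0, 1.0 - cz * cz));
    ux = sz * std::cos(th); uy = sz * std::sin(th); uz = cz;
    d = 1.0;
  } else {
    ux /= d; uy /= d; uz /= d;
  }
  double mag = 0.0;
  if (d < Rsum) {
    double s = 1.0 - d / Rsum;
    mag = std::sqrt(ccr_a * ccr_b) * s * s;       // repulsive, away from b
  } else {
    double s = 1.0 - d / Rmax;
    mag = -cca * s * s;                           // adhesive, toward b
  }
  out[0] = mag * ux; out[1] = mag * uy; out[2] = mag * uz;
  return true;
}

// [[Rcpp::export]]
NumericVector cpp_pair_force(NumericVector a, NumericVector b,
                             double Ra, double Rb, double ccr_a, double ccr_b,
                             double cca, double adh_scale) {
  double out[3];
  int cc = 0;
  pair_velocity(a[0], a[1], a[2], b[0], b[1], b[2], Ra, Rb, ccr_a, ccr_b,
                cca, adh_scale, out, &cc);
  return NumericVector::create(out[0], out[1], out[2]);
}

// Uniform-bin neighbour grid over point sets.
struct BinGrid {
  double edge, Lx, Ly, Lz;
  int bx, by, bz;
  std::vector<std::vector<int>> bins;
  void build(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z, int n_used,
             double edge_, double Lx_, double Ly_, double Lz_) {
    edge = edge_; Lx = Lx_; Ly = Ly_; Lz = Lz_;
    bx = std::max(1, (int)std::ceil(Lx / edge));
    by = std::max(1, (int)std::ceil(Ly / edge));
    bz = std::max(1, (int)std::ceil(Lz / edge));
    bins.assign((size_t)bx * by * bz, {});
    for (int i = 0; i < n_used; ++i) insert(i, x[i], y[i], z[i]);
  }
  int bidx(double x, double y, double z) const {
    int i = std::min(bx - 1, std::max(0, (int)std::floor(x / edge)));
    int j = std::min(by - 1, std::max(0, (int)std::floor(y / edge)));
    int k = std::min(bz - 1, std::max(0, (int)std::floor(z / edge)));
    return i + bx * (j + by * k);
  }
  void insert(int id, double x, double y, double z) {
    bins[bidx(x, y, z)].push_back(id);
  }
  // visit all candidates within `reach` bins of (x,y,z)
  template <typename F>
  void visit(double x, double y, double z, double radius, F f) const {
    int reach = std::max(1, (int)std::ceil(radius / edge));
    int ic = std::min(bx - 1, std::max(0, (int)std::floor(x / edge)));
    int jc = std::min(by - 1, std::max(0, (int)std::floor(y / edge)));
    int kc = std::min(bz - 1, std::max(0, (int)std::floor(z / edge)));
    for (int k = std::max(0, kc - reach); k <= std::min(bz - 1, kc + reach); ++k)
      for (int j = std::max(0, jc - reach); j <= std::min(by - 1, jc + reach); ++j)
        for (int i = std::max(0, ic - reach); i <= std::min(bx - 1, ic + reach); ++i)
          for (int id : bins[i + bx * (j + by * k)]) f(id);
  }
};

// [[Rcpp::export]]
List cpp_neighbors(NumericMatrix pos, NumericMatrix query, double radius,
                   double bin_edge, NumericVector domain) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  BinGrid bg;
  bg.build(x, y, z, n, bin_edge, domain[0], domain[1], domain[2]);
  List out(query.nrow());
  double r2 = radius * radius;
  for (int q = 0; q < query.nrow(); ++q) {
    std::vector<int> hits;
    bg.visit(query(q, 0), query(q, 1), query(q, 2), radius, [&](int id) {
      double dxx = x[id] - query(q, 0), dyy = y[id] - query(q, 1),
             dzz = z[id] - query(q, 2);
      if (dxx * dxx + dyy * dyy + dzz * dzz <= r2) hits.push_back(id + 1);
    });
    std::sort(hits.begin(), hits.end());
    out[q] = wrap(hits);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_update_motion(NumericMatrix pos, NumericVector radius,
                       NumericVector ccr, double cca, double adh_scale,
                       NumericMatrix motility, LogicalVector frozen,
                       double dt, NumericVector domain, double bin_edge) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  BinGrid bg;
  bg.build(x, y, z, n, bin_edge, domain[0], domain[1], domain[2]);
  NumericMatrix newpos(n, 3), vel(n, 3);
  int clamped = 0, coincident = 0;
  double maxdisp = 0, maxR = 0;
  for (int i = 0; i < n; ++i) maxR = std::max(maxR, radius[i]);
  double reach = 2.0 * adh_scale * maxR;
  for (int i = 0; i < n; ++i) {
    double v[3] = {0, 0, 0}, f[3];
    bg.visit(x[i], y[i], z[i], reach, [&](int j) {
      if (j == i) return;
      if (pair_velocity(x[i], y[i], z[i], x[j], y[j], z[j], radius[i],
                        radius[j], ccr[i], ccr[j], cca, adh_scale, f,
                        &coincident)) {
        v[0] += f[0]; v[1] += f[1]; v[2] += f[2];
      }
    });
    if (!frozen[i]) {
      v[0] += motility(i, 0); v[1] += motility(i, 1); v[2] += motility(i, 2);
    }
    double nx_ = x[i] + v[0] * dt, ny_ = y[i] + v[1] * dt, nz_ = z[i] + v[2] * dt;
    double eps = 1e-6;
    for (int a = 0; a < 3; ++a) {
      double* p = a == 0 ? &nx_ : (a == 1 ? &ny_ : &nz_);
      if (*p < 0) { *p = 0; ++clamped; }
      if (*p >= domain[a]) { *p = domain[a] - eps; ++clamped; }
    }
    double dsp = std::sqrt((nx_ - x[i]) * (nx_ - x[i]) +
                           (ny_ - y[i]) * (ny_ - y[i]) +
                           (nz_ - z[i]) * (nz_ - z[i]));
    maxdisp = std::max(maxdisp, dsp);
    newpos(i, 0) = nx_; newpos(i, 1) = ny_; newpos(i, 2) = nz_;
    vel(i, 0) = v[0]; vel(i, 1) = v[1]; vel(i, 2) = v[2];
  }
  return List::create(_["position"] = newpos, _["velocity"] = vel,
                      _["clamped"] = clamped, _["max_displacement"] = maxdisp,
                      _["coincident"] = coincident);
}

// ---------------------------------------------------------------------------
// Simulation engine
// ---------------------------------------------------------------------------

struct Engine {
  // --- configuration ---
  double L;                      // cubic domain edge (um)
  GridDims grid;                 // microenvironment mesh
  double mech_edge;              // mechanics bin edge (um)
  double dt_cycle, dt_mech, dt_diff, t_save, t_total;
  int t_v_steps;
  // substrates: 0 = oxygen, 1 = immunostimulatory factor
  double D_o2, lam_o2, init_o2, boundary_o2;   // boundary_o2 < 0: no shell
  double D_if, lam_if, init_if, sat_if;
  // cancer cells
  double R_cell, V_ref, ccr_cancer, cca, adh_scale, nu;
  double O_uptake_cancer, IF_secretion;
  double T_G1, T_S, T_G2, T_M;   // minutes
  double o2_arrest, o2_sat, o2_necrosis, tau_necrosis;
  double vol_rate, vol_rate_apop, vol_rate_necro, removal_fraction;
  bool fixed_phase;
  // immune cells
  double ccr_tcell, O_uptake_tcell, v_mot, bias, t_per, t_attach;
  double r_kill, r_adh, R_LA, life_mean, life_sd;
  double o_recog;
  bool multi_antigen, long_term, angles_uniform;
  // dosing
  std::vector<double> dose_day;
  std::vector<double> dose_ratio;

  // --- state ---
  std::vector<double> o2, ifc;           // substrate fields
  std::vector<int> shell_idx;            // boundary Dirichlet voxels (oxygen)
  // cancer (struct of arrays)
  std::vector<double> cx, cy, cz, cV, co, cclock;
  std::vector<int> cphase, cdeath, cattached, ctype;
  // T cells
  std::vector<double> tx, ty, tz, tdx, tdy, tdz, trx, try_, trz;
  std::vector<double> tage, tlife, tclock, tmx, tmy, tmz;
  std::vector<int> ttarget, tid, tdose;
  // persistent per-T ledger (indexed by tid)
  std::vector<int> led_dose;
  std::vector<double> led_dose_day, led_life;
  std::vector<int> led_kills;
  std::vector<double> led_exhausted_day;   // NA -> -1
  // counters
  double time = 0;
  long cum_dead = 0, cum_kills = 0, cum_dead_hypoxia = 0, cum_born = 0;
  long clamp_events = 0, coincident_pairs = 0, big_disp_events = 0;
  long kills_by_type[4] = {0, 0, 0, 0};
  int dose_base_N = -1;
  std::vector<bool> dose_given;
  std::vector<long> dose_kills;         // cumulative kills per dose index
  BinGrid bg;
  bool pop_changed = true;
  int mech_counter = 0;
  ThomasAxis ax_o2[3], ax_if[3];   // cached tridiagonal coefficients
  // Verlet pair list (rebuilt with the neighbour grid); indices over the
  // combined population (cancer first, then T cells)
  std::vector<int> pair_i, pair_j;
  std::vector<double> fvx, fvy, fvz;   // per-agent velocity accumulators
  double verlet_skin = 6.0;            // um
  double acc_disp = 0.0;               // max displacement since last build

  // --- helpers ---
  static double norm3(double a, double b, double c) {
    return std::sqrt(a * a + b * b + c * c);
  }
  double radius_of(double V) const {
    return std::cbrt(3.0 * V / (4.0 * M_PI));
  }
  int cell_type(double o) const {
    if (o >= 1.5) return 1;
    if (o >= 1.0) return 2;
    if (o >= 0.5) return 3;
    return 4;
  }
  double immunog(double o) const {
    if (multi_antigen) return 1.0;
    return o < o_recog ? 0.0 : o;
  }
  void random_dir(double& a, double& b, double& c) const {
    if (angles_uniform) {
      double th = 2.0 * M_PI * unif_rand();
      double cz = 2.0 * unif_rand() - 1.0;
      double sz = std::sqrt(std::max(0.0, 1.0 - cz * cz));
      a = sz * std::cos(th); b = sz * std::sin(th); c = cz;
    } else {
      // as printed in the source model description: theta ~ U[0,pi] in the
      // azimuth slot, phi ~ U[0,2pi] in the polar slot (not area-uniform)
      double th = M_PI * unif_rand();
      double ph = 2.0 * M_PI * unif_rand();
      a = std::sin(ph) * std::cos(th);
      b = std::sin(ph) * std::sin(th);
      c = std::cos(ph);
    }
  }
  double draw_lifespan() const {
    if (long_term) return INF;
    for (int tries = 0; tries < 10000; ++tries) {
      double v = life_mean + life_sd * norm_rand();
      if (v > 0) return v;
    }
    return life_mean;
  }

  void setup_substrates() {
    o2.assign(grid.n(), init_o2);
    ifc.assign(grid.n(), init_if);
    shell_idx.clear();
    if (boundary_o2 >= 0) {
      for (int k = 0; k < grid.nz; ++k)
        for (int j = 0; j < grid.ny; ++j)
          for (int i = 0; i < grid.nx; ++i)
            if (i == 0 || j == 0 || k == 0 || i == grid.nx - 1 ||
                j == grid.ny - 1 || k == grid.nz - 1)
              shell_idx.push_back(grid.idx(i, j, k));
    }
    int ns[3] = {grid.nx, grid.ny, grid.nz};
    for (int a = 0; a < 3; ++a) {
      ax_o2[a].init(ns[a], D_o2 * dt_diff / (dx2()));
      ax_if[a].init(ns[a], D_if * dt_diff / (dx2()));
    }
  }
  double dx2() const { return grid.dx * grid.dx; }

  void diffusion_substep() {
    lod_diffusion_step_cached(o2.data(), grid, D_o2, lam_o2, dt_diff,
                              ax_o2[0], ax_o2[1], ax_o2[2]);
    lod_diffusion_step_cached(ifc.data(), grid, D_if, lam_if, dt_diff,
                              ax_if[0], ax_if[1], ax_if[2]);
    for (int v : shell_idx) o2[v] = boundary_o2;
    // secretion/uptake, nearest-voxel lumping
    double vvox = grid.dx * grid.dx * grid.dx;
    for (size_t i = 0; i < cx.size(); ++i) {
      if (cdeath[i] != 0) continue;      // dead cells neither secrete nor uptake
      int v = grid.voxel_of(cx[i], cy[i], cz[i]);
      double rho = cV[i] / vvox;
      exchange_voxel(o2[v], 0.0, O_uptake_cancer, 0.0, rho, dt_diff);
      exchange_voxel(ifc[v], IF_secretion, 0.0, sat_if, rho, dt_diff);
    }
    for (size_t i = 0; i < tx.size(); ++i) {
      int v = grid.voxel_of(tx[i], ty[i], tz[i]);
      exchange_voxel(o2[v], 0.0, O_uptake_tcell, 0.0, V_ref / vvox, dt_diff);
    }
  }

  void detach(int ti) {
    int tgt = ttarget[ti];
    if (tgt >= 0 && cattached[tgt] > 0) cattached[tgt]--;
    ttarget[ti] = -1;
    tclock[ti] = 0;
  }

  void remove_tcell(int ti) {
    int last = (int)tx.size() - 1;
    tx[ti] = tx[last]; ty[ti] = ty[last]; tz[ti] = tz[last];
    tdx[ti] = tdx[last]; tdy[ti] = tdy[last]; tdz[ti] = tdz[last];
    trx[ti] = trx[last]; try_[ti] = try_[last]; trz[ti] = trz[last];
    tage[ti] = tage[last]; tlife[ti] = tlife[last]; tclock[ti] = tclock[last];
    tmx[ti] = tmx[last]; tmy[ti] = tmy[last]; tmz[ti] = tmz[last];
    ttarget[ti] = ttarget[last]; tid[ti] = tid[last]; tdose[ti] = tdose[last];
    tx.pop_back(); ty.pop_back(); tz.pop_back();
    tdx.pop_back(); tdy.pop_back(); tdz.pop_back();
    trx.pop_back(); try_.pop_back(); trz.pop_back();
    tage.pop_back(); tlife.pop_back(); tclock.pop_back();
    tmx.pop_back(); tmy.pop_back(); tmz.pop_back();
    ttarget.pop_back(); tid.pop_back(); tdose.pop_back();
    pop_changed = true;
  }

  void remove_cancer(int ci) {
    // any T cell still pointing here (or at the index being moved) is patched
    int last = (int)cx.size() - 1;
    for (size_t t = 0; t < ttarget.size(); ++t) {
      if (ttarget[t] == ci) detach((int)t);
      if (ttarget[t] == last) ttarget[t] = ci;
    }
    cx[ci] = cx[last]; cy[ci] = cy[last]; cz[ci] = cz[last];
    cV[ci] = cV[last]; co[ci] = co[last]; cclock[ci] = cclock[last];
    cphase[ci] = cphase[last]; cdeath[ci] = cdeath[last];
    cattached[ci] = cattached[last]; ctype[ci] = ctype[last];
    cx.pop_back(); cy.pop_back(); cz.pop_back();
    cV.pop_back(); co.pop_back(); cclock.pop_back();
    cphase.pop_back(); cdeath.pop_back(); cattached.pop_back();
    ctype.pop_back();
    pop_changed = true;
  }

  void kill_cancer(int tgt, int ti) {
    cdeath[tgt] = 1;       // apoptosis
    ++cum_dead;
    ++cum_kills;
    kills_by_type[ctype[tgt] - 1]++;
    led_kills[tid[ti]]++;
    dose_kills[tdose[ti]]++;
    detach(ti);
  }

  void immune_substep() {
    double half_day = 1440.0;
    for (int i = (int)tx.size() - 1; i >= 0; --i) {
      tage[i] += dt_mech;
      if (!long_term && tage[i] > tlife[i]) {
        led_exhausted_day[tid[i]] = time / half_day;
        if (ttarget[i] >= 0) detach(i);
        remove_tcell(i);
        continue;
      }
      if (ttarget[i] >= 0) {
        int tgt = ttarget[i];
        if (cdeath[tgt] != 0) {          // target already dead: no kill
          detach(i);
        } else {
          tclock[i] += dt_mech;
          double p = std::min(1.0, r_kill * dt_mech * immunog(co[tgt]));
          if (p > 0 && unif_rand() < p) {
            kill_cancer(tgt, i);
          } else if (tclock[i] >= t_attach) {
            detach(i);                   // attachment timeout, no apoptosis
          }
        }
        tmx[i] = tmy[i] = tmz[i] = 0;    // motility off while attached
        continue;
      }
      // direction resampling
      if (unif_rand() < dt_mech / t_per)
        random_dir(trx[i], try_[i], trz[i]);
      // chemotaxis direction from the immunostimulatory gradient
      double g[3];
      gradient_at(ifc.data(), grid, tx[i], ty[i], tz[i], g);
      double gn = norm3(g[0], g[1], g[2]);
      if (gn > 0) { tdx[i] = g[0] / gn; tdy[i] = g[1] / gn; tdz[i] = g[2] / gn; }
      double bx_ = bias * tdx[i] + (1 - bias) * trx[i];
      double by_ = bias * tdy[i] + (1 - bias) * try_[i];
      double bz_ = bias * tdz[i] + (1 - bias) * trz[i];
      double bn = norm3(bx_, by_, bz_);
      if (bn > 1e-12) {
        tmx[i] = v_mot * bx_ / bn; tmy[i] = v_mot * by_ / bn;
        tmz[i] = v_mot * bz_ / bn;
      } else {
        tmx[i] = v_mot * trx[i]; tmy[i] = v_mot * try_[i];
        tmz[i] = v_mot * trz[i];
      }
      // adhesion attempt: nearest eligible live target within R_LA
      int best = -1;
      double bestd = INF;
      bg.visit(tx[i], ty[i], tz[i], R_LA, [&](int id) {
        if (id >= (int)cx.size()) return;      // T-cell entry in the grid
        if (cdeath[id] != 0) return;
        if (!multi_antigen && co[id] < o_recog) return;
        double dxx = cx[id] - tx[i], dyy = cy[id] - ty[i], dzz = cz[id] - tz[i];
        double d = norm3(dxx, dyy, dzz);
        if (d <= R_LA && (d < bestd || (d == bestd && id < best))) {
          bestd = d; best = id;
        }
      });
      if (best >= 0 && unif_rand() < r_adh * dt_mech) {
        ttarget[i] = best;
        tclock[i] = 0;
        cattached[best]++;
        tmx[i] = tmy[i] = tmz[i] = 0;
      }
    }
  }

  void rebuild_grid() {
    int nc = (int)cx.size(), nt = (int)tx.size();
    std::vector<double> X(nc + nt), Y(nc + nt), Z(nc + nt);
    for (int i = 0; i < nc; ++i) { X[i] = cx[i]; Y[i] = cy[i]; Z[i] = cz[i]; }
    for (int i = 0; i < nt; ++i) {
      X[nc + i] = tx[i]; Y[nc + i] = ty[i]; Z[nc + i] = tz[i];
    }
    bg.build(X, Y, Z, nc + nt, mech_edge, L, L, L);
    // Verlet pairs: every pair whose interaction range plus skin covers the
    // current separation; valid until any agent has moved by skin/2
    pair_i.clear();
    pair_j.clear();
    std::vector<double> R(nc + nt);
    for (int i = 0; i < nc; ++i) R[i] = radius_of(cV[i]);
    for (int i = 0; i < nt; ++i) R[nc + i] = R_cell;
    double maxR = R_cell;
    for (int i = 0; i < nc + nt; ++i) maxR = std::max(maxR, R[i]);
    double search = 2.0 * adh_scale * maxR + verlet_skin;
    for (int i = 0; i < nc + nt; ++i) {
      bg.visit(X[i], Y[i], Z[i], search, [&](int j) {
        if (j <= i) return;
        double dxx = X[i] - X[j], dyy = Y[i] - Y[j], dzz = Z[i] - Z[j];
        double cut = adh_scale * (R[i] + R[j]) + verlet_skin;
        if (dxx * dxx + dyy * dyy + dzz * dzz < cut * cut) {
          pair_i.push_back(i);
          pair_j.push_back(j);
        }
      });
    }
    acc_disp = 0.0;
    pop_changed = false;
  }

  void mechanics_substep() {
    int nc = (int)cx.size(), nt = (int)tx.size(), n = nc + nt;
    if (n == 0) return;
    double eps = 1e-6;
    fvx.assign(n, 0.0); fvy.assign(n, 0.0); fvz.assign(n, 0.0);
    sx.resize(n); sy.resize(n); sz.resize(n); sR.resize(n); sC.resize(n);
    for (int i = 0; i < nc; ++i) {
      sx[i] = cx[i]; sy[i] = cy[i]; sz[i] = cz[i];
      sR[i] = radius_of(cV[i]); sC[i] = ccr_cancer;
    }
    for (int i = 0; i < nt; ++i) {
      sx[nc + i] = tx[i]; sy[nc + i] = ty[i]; sz[nc + i] = tz[i];
      sR[nc + i] = R_cell; sC[nc + i] = ccr_tcell;
    }
    double f[3];
    for (size_t p = 0; p < pair_i.size(); ++p) {
      int i = pair_i[p], j = pair_j[p];
      if (pair_velocity(sx[i], sy[i], sz[i], sx[j], sy[j], sz[j],
                        sR[i], sR[j], sC[i], sC[j], cca, adh_scale, f,
                        &coincident_pairs_int)) {
        fvx[i] += f[0]; fvy[i] += f[1]; fvz[i] += f[2];
        fvx[j] -= f[0]; fvy[j] -= f[1]; fvz[j] -= f[2];
      }
    }
    // motility of unattached T cells
    for (int i = 0; i < nt; ++i) {
      if (ttarget[i] < 0) {
        fvx[nc + i] += tmx[i]; fvy[nc + i] += tmy[i]; fvz[nc + i] += tmz[i];
      }
    }
    double step_max = 0.0;
    for (int i = 0; i < n; ++i) {
      double nx_ = sx[i] + fvx[i] * dt_mech;
      double ny_ = sy[i] + fvy[i] * dt_mech;
      double nz_ = sz[i] + fvz[i] * dt_mech;
      if (nx_ < 0) { nx_ = 0; ++clamp_events; }
      if (ny_ < 0) { ny_ = 0; ++clamp_events; }
      if (nz_ < 0) { nz_ = 0; ++clamp_events; }
      if (nx_ >= L) { nx_ = L - eps; ++clamp_events; }
      if (ny_ >= L) { ny_ = L - eps; ++clamp_events; }
      if (nz_ >= L) { nz_ = L - eps; ++clamp_events; }
      double dsp = norm3(nx_ - sx[i], ny_ - sy[i], nz_ - sz[i]);
      if (dsp > step_max) step_max = dsp;
      if (dsp > R_cell) ++big_disp_events;
      if (i < nc) { cx[i] = nx_; cy[i] = ny_; cz[i] = nz_; }
      else { tx[i - nc] = nx_; ty[i - nc] = ny_; tz[i - nc] = nz_; }
    }
    acc_disp += step_max;
    // pairs stay valid while no separation has shrunk by more than the skin;
    // trigger one step early to absorb the pre-rebuild displacement
    if (acc_disp > verlet_skin / 2.0 - 1.0) pop_changed = true;
  }
  int coincident_pairs_int = 0;
  std::vector<double> sx, sy, sz, sR, sC;   // per-substep scratch

  double phase_duration(int ph, double o, double f_o2) const {
    switch (ph) {
      case 0: {
        double s = o * f_o2;
        return s <= 0 ? INF : T_G1 / s;
      }
      case 1: return T_S;
      case 2: return T_G2;
      default: return T_M;
    }
  }

  void divide_cell(int i) {
    double Vd = cV[i] / 2.0;
    double ux, uy, uz;
    // division axis uniform on the sphere
    double th = 2.0 * M_PI * unif_rand();
    double czv = 2.0 * unif_rand() - 1.0;
    double szv = std::sqrt(std::max(0.0, 1.0 - czv * czv));
    ux = szv * std::cos(th); uy = szv * std::sin(th); uz = czv;
    double off = R_cell / 2.0;
    double mx = cx[i], my = cy[i], mz = cz[i];
    auto clampd = [&](double v) {
      return std::min(std::max(v, 0.0), L - 1e-6);
    };
    cx[i] = clampd(mx - ux * off); cy[i] = clampd(my - uy * off);
    cz[i] = clampd(mz - uz * off);
    cV[i] = Vd; cphase[i] = 0; cclock[i] = 0;
    cx.push_back(clampd(mx + ux * off));
    cy.push_back(clampd(my + uy * off));
    cz.push_back(clampd(mz + uz * off));
    cV.push_back(Vd);
    co.push_back(co[i]);          // oncoprotein inherited exactly
    cclock.push_back(0);
    cphase.push_back(0);
    cdeath.push_back(0);
    cattached.push_back(0);
    ctype.push_back(ctype[i]);
    ++cum_born;
    pop_changed = true;
  }

  void cycle_step() {
    double dtc = dt_cycle;
    for (int i = (int)cx.size() - 1; i >= 0; --i) {
      if (cdeath[i] != 0) {
        double r = cdeath[i] == 1 ? vol_rate_apop : vol_rate_necro;
        cV[i] = cV[i] / (1.0 + r * dtc);      // implicit relaxation toward 0
        if (cV[i] < removal_fraction * V_ref) remove_cancer(i);
        continue;
      }
      double O2 = o2[grid.voxel_of(cx[i], cy[i], cz[i])];
      if (O2 < o2_necrosis && unif_rand() < dtc / tau_necrosis) {
        cdeath[i] = 2;
        ++cum_dead;
        ++cum_dead_hypoxia;
        continue;
      }
      // volume relaxation toward the division target
      double Vt = 2.0 * V_ref;
      cV[i] = (cV[i] + vol_rate * dtc * Vt) / (1.0 + vol_rate * dtc);
      if (cattached[i] > 0) continue;         // cycling frozen under attack
      double f_o2 = (O2 - o2_arrest) / (o2_sat - o2_arrest);
      f_o2 = std::min(1.0, std::max(0.0, f_o2));
      double Tdur = phase_duration(cphase[i], co[i], f_o2);
      bool exit_phase;
      if (fixed_phase) {
        cclock[i] += dtc;
        exit_phase = std::isfinite(Tdur) && cclock[i] >= Tdur;
      } else {
        exit_phase = std::isfinite(Tdur) && unif_rand() < std::min(1.0, dtc / Tdur);
      }
      if (exit_phase) {
        cclock[i] = 0;
        if (cphase[i] == 3) divide_cell(i);
        else cphase[i]++;
      }
    }
  }

  void administer_dose(int k) {
    int live = 0;
    double comx = 0, comy = 0, comz = 0;
    for (size_t i = 0; i < cx.size(); ++i)
      if (cdeath[i] == 0) { ++live; comx += cx[i]; comy += cy[i]; comz += cz[i]; }
    if (live > 0) { comx /= live; comy /= live; comz /= live; }
    int N;
    if (dose_base_N < 0) {
      N = (int)std::lround(dose_ratio[k] * live);
      dose_base_N = N;
    } else {
      // later doses deliver the same absolute count scale per unit ratio
      N = (int)std::lround(dose_ratio[k] * dose_base_N / dose_ratio[0]);
    }
    double Rb = 0;
    for (size_t i = 0; i < cx.size(); ++i)
      if (cdeath[i] == 0)
        Rb = std::max(Rb, norm3(cx[i] - comx, cy[i] - comy, cz[i] - comz));
    double margin = Rb + 2.0 * R_cell;
    for (int q = 0; q < N; ++q) {
      double px = 0, py = 0, pz = 0;
      bool ok = false;
      for (int tries = 0; tries < 2000 && !ok; ++tries) {
        px = unif_rand() * L; py = unif_rand() * L; pz = unif_rand() * L;
        ok = norm3(px - comx, py - comy, pz - comz) > margin;
      }
      tx.push_back(px); ty.push_back(py); tz.push_back(pz);
      double a, b, c;
      random_dir(a, b, c);
      trx.push_back(a); try_.push_back(b); trz.push_back(c);
      tdx.push_back(a); tdy.push_back(b); tdz.push_back(c);
      tage.push_back(0);
      tlife.push_back(draw_lifespan());
      tclock.push_back(0);
      tmx.push_back(0); tmy.push_back(0); tmz.push_back(0);
      ttarget.push_back(-1);
      int id = (int)led_dose.size();
      tid.push_back(id);
      tdose.push_back(k);
      led_dose.push_back(k);
      led_dose_day.push_back(time / 1440.0);
      led_life.push_back(tlife.back());
      led_kills.push_back(0);
      led_exhausted_day.push_back(-1);
    }
    pop_changed = true;
  }
};

static double cfg_d(const List& cfg, const char* key) {
  return as<double>(cfg[key]);
}

// [[Rcpp::export]]
List cpp_run_engine(List cfg, List init, bool save_snapshots) {
  Engine e;
  e.L = cfg_d(cfg, "domain_size");
  double dx = cfg_d(cfg, "voxel_size");
  int nvox = (int)std::lround(e.L / dx);
  e.grid.nx = e.grid.ny = e.grid.nz = nvox;
  e.grid.dx = dx;
  e.mech_edge = cfg_d(cfg, "mech_voxel_size");
  e.dt_cycle = cfg_d(cfg, "dt_cycle");
  e.dt_mech = cfg_d(cfg, "dt_mech");
  e.dt_diff = cfg_d(cfg, "dt_diff");
  e.t_save = cfg_d(cfg, "t_save");
  e.t_total = cfg_d(cfg, "t_total");
  e.t_v_steps = (int)cfg_d(cfg, "t_v_steps");
  e.D_o2 = cfg_d(cfg, "oxygen_diffusion");
  e.lam_o2 = cfg_d(cfg, "oxygen_decay");
  e.init_o2 = cfg_d(cfg, "oxygen_init");
  e.boundary_o2 = cfg_d(cfg, "oxygen_boundary");
  e.D_if = cfg_d(cfg, "if_diffusion");
  e.lam_if = cfg_d(cfg, "if_decay");
  e.init_if = cfg_d(cfg, "if_init");
  e.sat_if = cfg_d(cfg, "if_saturation");
  e.R_cell = cfg_d(cfg, "cell_radius");
  e.V_ref = 4.0 / 3.0 * M_PI * std::pow(e.R_cell, 3);
  e.nu = cfg_d(cfg, "nu");
  e.ccr_cancer = cfg_d(cfg, "repulsion_cancer") * e.nu;
  e.ccr_tcell = cfg_d(cfg, "repulsion_tcell") * e.nu;
  e.cca = cfg_d(cfg, "adhesion_strength");
  e.adh_scale = cfg_d(cfg, "adhesion_distance_scale");
  e.O_uptake_cancer = cfg_d(cfg, "oxygen_uptake_cancer");
  e.O_uptake_tcell = cfg_d(cfg, "oxygen_uptake_tcell");
  e.IF_secretion = cfg_d(cfg, "if_secretion");
  e.T_G1 = cfg_d(cfg, "T_G1");
  e.T_S = cfg_d(cfg, "T_S");
  e.T_G2 = cfg_d(cfg, "T_G2");
  e.T_M = cfg_d(cfg, "T_M");
  e.o2_arrest = cfg_d(cfg, "o2_proliferation_arrest");
  e.o2_sat = cfg_d(cfg, "o2_proliferation_saturation");
  e.o2_necrosis = cfg_d(cfg, "o2_necrosis_threshold");
  e.tau_necrosis = cfg_d(cfg, "tau_necrosis");
  e.vol_rate = cfg_d(cfg, "volume_rate");
  e.vol_rate_apop = cfg_d(cfg, "volume_rate_apoptosis");
  e.vol_rate_necro = cfg_d(cfg, "volume_rate_necrosis");
  e.removal_fraction = cfg_d(cfg, "removal_fraction");
  e.fixed_phase = as<bool>(cfg["fixed_phase_durations"]);
  e.v_mot = cfg_d(cfg, "migration_speed");
  e.bias = cfg_d(cfg, "migration_bias");
  e.t_per = cfg_d(cfg, "persistence_time");
  e.t_attach = cfg_d(cfg, "attachment_time");
  e.r_kill = cfg_d(cfg, "kill_rate");
  e.r_adh = cfg_d(cfg, "adhesion_rate");
  e.R_LA = cfg_d(cfg, "max_adhesion_distance");
  e.life_mean = cfg_d(cfg, "lifespan_mean") * 1440.0;   // days -> minutes
  e.life_sd = cfg_d(cfg, "lifespan_sd") * 1440.0;
  e.o_recog = cfg_d(cfg, "recognition_threshold");
  e.multi_antigen = as<std::string>(cfg["recognition_mode"]) == "multi_antigen";
  e.long_term = as<std::string>(cfg["persistence_mode"]) == "long_term";
  e.angles_uniform = as<bool>(cfg["angles_uniform"]);
  NumericVector dd = cfg["dose_days"], dr = cfg["dose_ratios"];
  for (int i = 0; i < dd.size(); ++i) {
    e.dose_day.push_back(dd[i]);
    e.dose_ratio.push_back(dr[i]);
  }
  e.dose_given.assign(e.dose_day.size(), false);
  e.dose_kills.assign(std::max((size_t)1, e.dose_day.size()), 0);

  // initial cancer population
  NumericVector ix = init["x"], iy = init["y"], iz = init["z"],
                io = init["o"], iV = init["volume"], icl = init["phase_clock"];
  IntegerVector iph = init["phase"];
  int n0 = ix.size();
  for (int i = 0; i < n0; ++i) {
    e.cx.push_back(ix[i]); e.cy.push_back(iy[i]); e.cz.push_back(iz[i]);
    e.cV.push_back(iV[i]); e.co.push_back(io[i]);
    e.cclock.push_back(icl[i]);
    e.cphase.push_back(iph[i] - 1);       // R phases are 1..4
    e.cdeath.push_back(0);
    e.cattached.push_back(0);
    e.ctype.push_back(e.cell_type(io[i]));
  }
  e.setup_substrates();
  e.rebuild_grid();

  int n_mech = (int)std::lround(e.dt_cycle / e.dt_mech);
  int n_diff = (int)std::lround(e.dt_mech / e.dt_diff);
  int n_cycle = (int)std::lround(e.t_total / e.dt_cycle);

  std::vector<double> m_time, m_mean_o;
  std::vector<long> m_live, m_dead, m_tcell, m_kills, m_dead_hyp;
  std::vector<double> m_f1, m_f2, m_f3, m_f4;
  std::vector<std::vector<long>> m_dose_kills;
  List snapshots;
  std::vector<double> snap_times;
  List snap_list = List::create();

  auto record = [&]() {
    long live = 0;
    double sum_o = 0;
    long tc[4] = {0, 0, 0, 0};
    for (size_t i = 0; i < e.cx.size(); ++i) {
      if (e.cdeath[i] == 0) {
        ++live;
        sum_o += e.co[i];
        tc[e.ctype[i] - 1]++;
      }
    }
    m_time.push_back(e.time);
    m_live.push_back(live);
    m_dead.push_back(e.cum_dead);
    m_dead_hyp.push_back(e.cum_dead_hypoxia);
    m_mean_o.push_back(live > 0 ? sum_o / live : NA_REAL);
    for (int q = 0; q < 4; ++q) {
      double f = live > 0 ? (double)tc[q] / live : NA_REAL;
      (q == 0 ? m_f1 : q == 1 ? m_f2 : q == 2 ? m_f3 : m_f4).push_back(f);
    }
    m_tcell.push_back((long)e.tx.size());
    m_kills.push_back(e.cum_kills);
    m_dose_kills.push_back(std::vector<long>(e.dose_kills.begin(),
                                             e.dose_kills.end()));
  };

  auto snapshot_cancer = [&]() {
    int n = (int)e.cx.size();
    NumericMatrix m(n, 7);
    for (int i = 0; i < n; ++i) {
      m(i, 0) = e.cx[i]; m(i, 1) = e.cy[i]; m(i, 2) = e.cz[i];
      m(i, 3) = e.radius_of(e.cV[i]); m(i, 4) = e.co[i];
      m(i, 5) = e.cphase[i] + 1; m(i, 6) = e.cdeath[i];
    }
    colnames(m) = CharacterVector::create("x", "y", "z", "radius",
                                          "oncoprotein", "phase", "death");
    return m;
  };
  auto snapshot_tcells = [&]() {
    int n = (int)e.tx.size();
    NumericMatrix m(n, 6);
    for (int i = 0; i < n; ++i) {
      m(i, 0) = e.tx[i]; m(i, 1) = e.ty[i]; m(i, 2) = e.tz[i];
      m(i, 3) = e.tage[i] / 1440.0; m(i, 4) = e.led_kills[e.tid[i]];
      m(i, 5) = e.ttarget[i] >= 0 ? 1 : 0;
    }
    colnames(m) = CharacterVector::create("x", "y", "z", "age_days", "kills",
                                          "attached");
    return m;
  };

  record();
  if (save_snapshots) {
    snap_times.push_back(0);
    snap_list.push_back(List::create(_["cancer"] = snapshot_cancer(),
                                     _["tcells"] = snapshot_tcells()));
  }
  double next_save = e.t_save;

  for (int step = 0; step < n_cycle; ++step) {
    // dose checks at the cycle cadence
    for (size_t k = 0; k < e.dose_day.size(); ++k) {
      if (!e.dose_given[k] && e.time >= e.dose_day[k] * 1440.0 - 1e-9) {
        e.administer_dose((int)k);
        e.dose_given[k] = true;
      }
    }
    e.cycle_step();
    if (e.pop_changed) e.rebuild_grid();
    for (int m = 0; m < n_mech; ++m) {
      for (int q = 0; q < n_diff; ++q) e.diffusion_substep();
      e.immune_substep();
      if (e.pop_changed) e.rebuild_grid();
      e.mechanics_substep();
      if (++e.mech_counter % e.t_v_steps == 0) e.rebuild_grid();
    }
    e.time = (step + 1) * e.dt_cycle;
    if (e.time >= next_save - 1e-9) {
      record();
      if (save_snapshots) {
        snap_times.push_back(e.time);
        snap_list.push_back(List::create(_["cancer"] = snapshot_cancer(),
                                         _["tcells"] = snapshot_tcells()));
      }
      while (next_save <= e.time + 1e-9) next_save += e.t_save;
    }
    if (step % 50 == 0) Rcpp::checkUserInterrupt();
  }

  // metrics table
  int ns = (int)m_time.size();
  int ndose = (int)e.dose_kills.size();
  NumericMatrix dosek(ns, ndose);
  for (int r = 0; r < ns; ++r)
    for (int c = 0; c < ndose; ++c)
      dosek(r, c) = (double)m_dose_kills[r][c];
  List metrics = List::create(
      _["time"] = wrap(m_time), _["live_cancer"] = wrap(m_live),
      _["cum_dead"] = wrap(m_dead), _["cum_dead_hypoxia"] = wrap(m_dead_hyp),
      _["mean_oncoprotein"] = wrap(m_mean_o), _["frac_type1"] = wrap(m_f1),
      _["frac_type2"] = wrap(m_f2), _["frac_type3"] = wrap(m_f3),
      _["frac_type4"] = wrap(m_f4), _["live_tcells"] = wrap(m_tcell),
      _["cum_kills"] = wrap(m_kills));

  int nled = (int)e.led_dose.size();
  NumericVector lv_life(nled), lv_exh(nled), lv_day(nled);
  IntegerVector lv_dose(nled), lv_kills(nled), lv_id(nled);
  for (int i = 0; i < nled; ++i) {
    lv_id[i] = i + 1;
    lv_dose[i] = e.led_dose[i] + 1;
    lv_day[i] = e.led_dose_day[i];
    lv_life[i] = std::isfinite(e.led_life[i]) ? e.led_life[i] / 1440.0 : NA_REAL;
    lv_kills[i] = e.led_kills[i];
    lv_exh[i] = e.led_exhausted_day[i] < 0 ? NA_REAL : e.led_exhausted_day[i];
  }
  List ledger = List::create(_["tcell_id"] = lv_id, _["dose"] = lv_dose,
                             _["dose_day"] = lv_day,
                             _["lifespan_days"] = lv_life,
                             _["kills"] = lv_kills,
                             _["exhausted_day"] = lv_exh);

  return List::create(
      _["metrics"] = metrics, _["kill_ledger"] = ledger,
      _["dose_kills"] = dosek,
      _["final_cancer"] = snapshot_cancer(),
      _["final_tcells"] = snapshot_tcells(),
      _["final_oncoprotein"] = wrap(e.co),
      _["final_death"] = wrap(e.cdeath),
      _["kills_by_type"] = NumericVector::create(
          (double)e.kills_by_type[0], (double)e.kills_by_type[1],
          (double)e.kills_by_type[2], (double)e.kills_by_type[3]),
      _["counters"] = List::create(
          _["cum_born"] = (double)e.cum_born,
          _["cum_dead"] = (double)e.cum_dead,
          _["cum_kills"] = (double)e.cum_kills,
          _["cum_dead_hypoxia"] = (double)e.cum_dead_hypoxia,
          _["clamp_events"] = (double)e.clamp_events,
          _["big_displacement_events"] = (double)e.big_disp_events,
          _["tcells_administered"] = (double)nled,
          _["dose_base_n"] = (double)e.dose_base_N),
      _["snapshot_times"] = wrap(snap_times),
      _["snapshots"] = snap_list);
}
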