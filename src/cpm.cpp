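// Cellular Potts core: Metropolis copy kinetics on a 3D lattice with
// volume/surface elasticity, type-pair interface energies (including the
// mitotic-rounding adhesion schedules), a chemotactic move bias coupled to
// a scalar field, explicit reaction-diffusion stepping of that field, and
// clock-driven cell division.
//
// Site indexing is column-major and matches R's array layout:
//   idx = x + Lx * (y + Ly * z), 0-based here, 1-based on the R side.
// Boundary conditions: periodic in x and y; z = 0 is the frozen matrix
// (substrate) plane and z = Lz-1 a frozen medium plane, so no copy attempt
// ever targets either; the field is no-flux at matrix sites and at the top.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

// cell-type codes shared with the R side
enum CellType { T_MEDIUM = 0, T_CORE = 1, T_BODY = 2, T_TUMOR = 3, T_MATRIX = 4 };

// ---------------------------------------------------------------------------
// deterministic RNG (xorshift128+ seeded by splitmix64); avoids std::
// distributions whose streams are implementation-defined
struct Rng {
  uint64_t s0, s1;
  bool have_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) {
    // splitmix64 to spread a small seed over the state
    uint64_t z = seed;
    auto next = [&z]() {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      return t ^ (t >> 31);
    };
    s0 = next();
    s1 = next();
    if (s0 == 0 && s1 == 0) s0 = 1;
  }
  uint64_t next_u64() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  double unif() { return (next_u64() >> 11) * (1.0 / 9007199254740992.0); }
  // unbiased bounded integer in [0, n)
  int below(int n) {
    uint64_t x = next_u64();
    __uint128_t m = ( __uint128_t ) x * ( __uint128_t ) n;
    uint64_t l = (uint64_t) m;
    if (l < (uint64_t) n) {
      uint64_t t = (-(uint64_t) n) % (uint64_t) n;
      while (l < t) {
        x = next_u64();
        m = ( __uint128_t ) x * ( __uint128_t ) n;
        l = (uint64_t) m;
      }
    }
    return (int) (m >> 64);
  }
  double norm() {  // Box-Muller, cached pair
    if (have_spare) { have_spare = false; return spare; }
    double u1 = 0.0, u2;
    while (u1 <= 0.0) u1 = unif();
    u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    have_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

// ---------------------------------------------------------------------------
// neighbor tables: order-1 (6 faces) first, then the 12 order-2 (edge)
// offsets; -1 marks a neighbor beyond the z extent
static const int OFF18[18][3] = {
  { 1, 0, 0}, {-1, 0, 0}, { 0, 1, 0}, { 0,-1, 0}, { 0, 0, 1}, { 0, 0,-1},
  { 1, 1, 0}, { 1,-1, 0}, {-1, 1, 0}, {-1,-1, 0},
  { 1, 0, 1}, { 1, 0,-1}, {-1, 0, 1}, {-1, 0,-1},
  { 0, 1, 1}, { 0, 1,-1}, { 0,-1, 1}, { 0,-1,-1}
};

struct Geom {
  int Lx, Ly, Lz, N;
  std::vector<int> nbr;  // N x 18, -1 when out of z range
  void build(int lx, int ly, int lz) {
    Lx = lx; Ly = ly; Lz = lz; N = lx * ly * lz;
    nbr.assign((size_t) N * 18, -1);
    for (int z = 0; z < Lz; ++z)
      for (int y = 0; y < Ly; ++y)
        for (int x = 0; x < Lx; ++x) {
          int i = x + Lx * (y + Ly * z);
          for (int k = 0; k < 18; ++k) {
            int zz = z + OFF18[k][2];
            if (zz < 0 || zz >= Lz) continue;
            int xx = x + OFF18[k][0]; if (xx < 0) xx += Lx; else if (xx >= Lx) xx -= Lx;
            int yy = y + OFF18[k][1]; if (yy < 0) yy += Ly; else if (yy >= Ly) yy -= Ly;
            nbr[(size_t) i * 18 + k] = xx + Lx * (yy + Ly * zz);
          }
        }
  }
};

// ---------------------------------------------------------------------------
// full simulation state held natively during a run
struct Sim {
  Geom g;
  std::vector<int> grid;           // cell id per site
  std::vector<double> omega;       // chemoattractant
  // per-cell arrays, index = cell id (0 = medium)
  std::vector<int> type, gen;
  std::vector<double> Vt, Pt, t0, next_div, vol, surf;
  // energy parameters
  double J[5][5];
  double lamV, lamP, mu, temp;
  // rounding schedule: J_tt = rest_tt + sgn*amp*exp(-dt/tau_tt), same for tm
  double r_amp, r_tau_tt, r_tau_tm, r_window;
  int r_sgn;                       // -1 as printed, +1 weakening
  // rounding factors refreshed each MCS
  std::vector<double> rf_tt, rf_tm;

  bool frozen_site(int i) const {
    int z = i / (g.Lx * g.Ly);
    if (z == g.Lz - 1) return true;
    return type[grid[i]] == T_MATRIX;
  }

  void refresh_rounding(double t) {
    size_t n = type.size();
    rf_tt.assign(n, 0.0);
    rf_tm.assign(n, 0.0);
    for (size_t c = 1; c < n; ++c) {
      if (type[c] != T_TUMOR) continue;
      double dt = t - t0[c];
      if (t0[c] >= 0 && dt >= 0 && dt < r_window) {
        rf_tt[c] = std::exp(-dt / r_tau_tt);
        rf_tm[c] = std::exp(-dt / r_tau_tm);
      }
    }
  }

  // effective interface energy between two distinct cells a, b
  double Jeff(int a, int b) const {
    int ta = type[a], tb = type[b];
    double base = J[ta][tb];
    if (ta == T_TUMOR && tb == T_TUMOR) {
      double f = std::max(rf_tt[a], rf_tt[b]);  // most recent onset governs
      if (f > 0) base += r_sgn * r_amp * f;
    } else if ((ta == T_TUMOR && tb == T_MATRIX) || (ta == T_MATRIX && tb == T_TUMOR)) {
      double f = (ta == T_TUMOR) ? rf_tm[a] : rf_tm[b];
      if (f > 0) base += r_sgn * r_amp * f;
    }
    return base;
  }

  bool constrained(int c) const {
    return c > 0 && type[c] != T_MATRIX && type[c] != T_MEDIUM;
  }

  // incremental energy change for copying candidate id c into site s
  // (occupant o), candidate taken from neighbor site src
  double delta_h(int s, int src, int c) const {
    int o = grid[s];
    if (c == o) return 0.0;
    double dH = 0.0;
    if (constrained(o)) {
      double dv = vol[o] - Vt[o];
      dH += lamV * ((dv - 1.0) * (dv - 1.0) - dv * dv);
    }
    if (constrained(c)) {
      double dv = vol[c] - Vt[c];
      dH += lamV * ((dv + 1.0) * (dv + 1.0) - dv * dv);
    }
    // surface bookkeeping on the 6-face neighborhood
    int ko = 0, kc = 0;
    const int *nb = &g.nbr[(size_t) s * 18];
    for (int k = 0; k < 6; ++k) {
      int j = nb[k];
      int idn = (j >= 0) ? grid[j] : -1;
      if (idn == o) ++ko;
      if (idn == c) ++kc;
    }
    if (constrained(o)) {
      double dp = 2.0 * ko - 6.0, ds = surf[o] - Pt[o];
      dH += lamP * ((ds + dp) * (ds + dp) - ds * ds);
    }
    if (constrained(c)) {
      double dp = 6.0 - 2.0 * kc, ds = surf[c] - Pt[c];
      dH += lamP * ((ds + dp) * (ds + dp) - ds * ds);
    }
    // interface term over the order-2 neighborhood
    for (int k = 0; k < 18; ++k) {
      int j = nb[k];
      if (j < 0) continue;
      int idn = grid[j];
      if (idn != o) dH -= Jeff(o, idn);
      if (idn != c) dH += Jeff(c, idn);
    }
    // chemotactic bias applies when a tumor cell extends into the target
    if (type[c] == T_TUMOR && mu != 0.0)
      dH += mu * (omega[s] - omega[src]);
    return dH;
  }

  void apply_copy(int s, int c) {
    int o = grid[s];
    int ko = 0, kc = 0;
    const int *nb = &g.nbr[(size_t) s * 18];
    for (int k = 0; k < 6; ++k) {
      int j = nb[k];
      int idn = (j >= 0) ? grid[j] : -1;
      if (idn == o) ++ko;
      if (idn == c) ++kc;
    }
    grid[s] = c;
    vol[o] -= 1.0; vol[c] += 1.0;
    surf[o] += 2.0 * ko - 6.0;
    surf[c] += 6.0 - 2.0 * kc;
  }

  // total energy (constraints + interfaces, each unordered pair once);
  // the chemotactic term is a move difference and has no total counterpart
  double total_h() const {
    double H = 0.0;
    for (size_t c = 1; c < type.size(); ++c)
      if (constrained((int) c)) {
        double dv = vol[c] - Vt[c], ds = surf[c] - Pt[c];
        H += lamV * dv * dv + lamP * ds * ds;
      }
    // offsets 0,2,4,6,7,10,11,14,15 form one representative per +/- pair
    static const int POS[9] = {0, 2, 4, 6, 7, 10, 11, 14, 15};
    for (int i = 0; i < g.N; ++i) {
      int a = grid[i];
      const int *nb = &g.nbr[(size_t) i * 18];
      for (int k = 0; k < 9; ++k) {
        int j = nb[POS[k]];
        if (j < 0) continue;
        int b = grid[j];
        if (a != b) H += Jeff(a, b);
      }
    }
    return H;
  }

  void recount() {  // rebuild volume/surface caches from the grid
    std::fill(vol.begin(), vol.end(), 0.0);
    std::fill(surf.begin(), surf.end(), 0.0);
    for (int i = 0; i < g.N; ++i) vol[grid[i]] += 1.0;
    for (int i = 0; i < g.N; ++i) {
      int a = grid[i];
      if (a == 0) continue;
      const int *nb = &g.nbr[(size_t) i * 18];
      for (int k = 0; k < 6; ++k) {
        int j = nb[k];
        if (j < 0 || grid[j] != a) surf[a] += 1.0;
      }
    }
  }
};

// build a Sim from R-side pieces
static void sim_init(Sim &S, IntegerVector grid, NumericVector omega,
                     IntegerVector dims,
                     IntegerVector cell_type, NumericVector cell_Vt,
                     NumericVector cell_Pt, NumericVector cell_t0,
                     IntegerVector cell_gen, NumericVector cell_next_div,
                     NumericMatrix Jm, double lambda_V, double lambda_P,
                     double mu, double temp, int rounding_sign,
                     double rounding_amp, double tau_tt, double tau_tm,
                     double rounding_window) {
  S.g.build(dims[0], dims[1], dims[2]);
  if ((int) grid.size() != S.g.N) stop("grid does not match dims");
  S.grid.assign(grid.begin(), grid.end());
  if (omega.size() == 0) S.omega.assign(S.g.N, 0.0);
  else {
    if ((int) omega.size() != S.g.N) stop("omega does not match dims");
    S.omega.assign(omega.begin(), omega.end());
  }
  int ncell = cell_type.size();
  S.type.assign(ncell + 1, T_MEDIUM);
  S.gen.assign(ncell + 1, 0);
  S.Vt.assign(ncell + 1, 0.0); S.Pt.assign(ncell + 1, 0.0);
  S.t0.assign(ncell + 1, -1.0); S.next_div.assign(ncell + 1, R_PosInf);
  for (int c = 0; c < ncell; ++c) {
    S.type[c + 1] = cell_type[c];
    S.Vt[c + 1] = cell_Vt[c];
    S.Pt[c + 1] = cell_Pt[c];
    S.t0[c + 1] = cell_t0[c];
    S.gen[c + 1] = cell_gen[c];
    S.next_div[c + 1] = cell_next_div[c];
  }
  for (int a = 0; a < 5; ++a)
    for (int b = 0; b < 5; ++b) S.J[a][b] = Jm(a, b);
  S.lamV = lambda_V; S.lamP = lambda_P; S.mu = mu; S.temp = temp;
  S.r_sgn = rounding_sign; S.r_amp = rounding_amp;
  S.r_tau_tt = tau_tt; S.r_tau_tm = tau_tm; S.r_window = rounding_window;
  S.vol.assign(ncell + 1, 0.0);
  S.surf.assign(ncell + 1, 0.0);
  S.recount();
  for (int i = 0; i < S.g.N; ++i)
    if (S.grid[i] < 0 || S.grid[i] > ncell) stop("grid holds an unknown cell id");
}

// ---------------------------------------------------------------------------
// explicit forward-Euler reaction-diffusion substeps; no-flux at blocked
// (matrix) sites and at the z faces, periodic in x and y
static void field_substeps(std::vector<double> &om, const Geom &g,
                           const std::vector<uint8_t> &blocked,
                           const std::vector<uint8_t> &produce,
                           double p, double d, double D, double dt,
                           int n_substeps, double spacing) {
  std::vector<double> nw(om.size());
  const double Ddx2 = D / (spacing * spacing);
  const int Lx = g.Lx, Ly = g.Ly, Lz = g.Lz, Lxy = g.Lx * g.Ly;
  // planes with no blocked site in themselves or their z-neighbors take a
  // branch-free kernel (the substrate typically occupies only z = 0)
  std::vector<uint8_t> pb(Lz, 0);
  for (int z = 0; z < Lz; ++z)
    for (int i = z * Lxy; i < (z + 1) * Lxy; ++i)
      if (blocked[i]) { pb[z] = 1; break; }
  for (int s = 0; s < n_substeps; ++s) {
    for (int z = 0; z < Lz; ++z) {
      bool fast = !pb[z] && !(z > 0 && pb[z - 1]) && !(z < Lz - 1 && pb[z + 1]);
      if (fast) {
        // interior x runs branch-free so the compiler can vectorize it
        double wz = (z > 0 && z < Lz - 1) ? 2.0 : 1.0;
        int zm = (z > 0) ? -Lxy : Lxy, zp = (z < Lz - 1) ? Lxy : -Lxy;
        for (int y = 0; y < Ly; ++y) {
          int base = Lx * (y + Ly * z);
          int oy_m = (y == 0 ? Ly - 1 : y - 1) * Lx + Lxy * z - base;
          int oy_p = (y == Ly - 1 ? 0 : y + 1) * Lx + Lxy * z - base;
          auto upd = [&](int i, double xl, double xr) {
            double oi = om[i];
            double lap = xl + xr + om[i + oy_m] + om[i + oy_p] +
                         0.5 * wz * (om[i + zm] + om[i + zp]) -
                         (4.0 + wz) * oi;
            double prod = produce[i] ? p : 0.0;
            double v = oi + dt * (prod - d * oi + Ddx2 * lap);
            nw[i] = (v > 0.0) ? v : 0.0;
          };
          upd(base, om[base + Lx - 1], om[base + 1]);
          for (int x = 1; x < Lx - 1; ++x) {
            int i = base + x;
            upd(i, om[i - 1], om[i + 1]);
          }
          upd(base + Lx - 1, om[base + Lx - 2], om[base]);
        }
        continue;
      }
      for (int y = 0; y < Ly; ++y) {
        int base = Lx * (y + Ly * z);
        int oy_m = (y == 0 ? Ly - 1 : y - 1) * Lx + Lxy * z - base;
        int oy_p = (y == Ly - 1 ? 0 : y + 1) * Lx + Lxy * z - base;
        bool has_zm = z > 0, has_zp = z < Lz - 1;
        for (int x = 0; x < Lx; ++x) {
          int i = base + x;
          if (blocked[i]) { nw[i] = 0.0; continue; }
          double oi = om[i], lap = 0.0;
          int j = (x == 0 ? i + Lx - 1 : i - 1);
          if (!blocked[j]) lap += om[j] - oi;
          j = (x == Lx - 1 ? i - Lx + 1 : i + 1);
          if (!blocked[j]) lap += om[j] - oi;
          j = i + oy_m; if (!blocked[j]) lap += om[j] - oi;
          j = i + oy_p; if (!blocked[j]) lap += om[j] - oi;
          if (has_zm) { j = i - Lxy; if (!blocked[j]) lap += om[j] - oi; }
          if (has_zp) { j = i + Lxy; if (!blocked[j]) lap += om[j] - oi; }
          double prod = produce[i] ? p : 0.0;
          double v = oi + dt * (prod - d * oi + Ddx2 * lap);
          nw[i] = (v > 0.0) ? v : 0.0;
        }
      }
    }
    om.swap(nw);
  }
}

// [[Rcpp::export]]
NumericVector cpp_field_step(NumericVector omega, IntegerVector dims,
                             LogicalVector blocked, LogicalVector produce,
                             double p, double d, double D, double dt,
                             int n_substeps, double spacing) {
  Geom g; g.build(dims[0], dims[1], dims[2]);
  if ((int) omega.size() != g.N) stop("omega does not match dims");
  std::vector<double> om(omega.begin(), omega.end());
  std::vector<uint8_t> bl(g.N), pr(g.N);
  for (int i = 0; i < g.N; ++i) { bl[i] = blocked[i]; pr[i] = produce[i]; }
  field_substeps(om, g, bl, pr, p, d, D, dt, n_substeps, spacing);
  NumericVector out(om.begin(), om.end());
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// division helper: partition a cell's sites by a vertical plane through the
// periodic centroid with horizontal normal (cos az, sin az); sites on the
// non-negative side move to new_id
struct SplitResult { int n_kept, n_new; double cx, cy, cz; };

static SplitResult split_cell(std::vector<int> &grid, const Geom &g,
                              int cell_id, int new_id, double az) {
  std::vector<int> sites;
  for (int i = 0; i < g.N; ++i)
    if (grid[i] == cell_id) sites.push_back(i);
  SplitResult r; r.n_kept = 0; r.n_new = 0; r.cx = r.cy = r.cz = NA_REAL;
  if (sites.size() < 2) return r;
  // periodic (circular-mean) centroid in x and y, plain mean in z
  double sx = 0, cx = 0, sy = 0, cy = 0, sz = 0;
  for (int i : sites) {
    int x = i % g.Lx, y = (i / g.Lx) % g.Ly, z = i / (g.Lx * g.Ly);
    double ax = 2.0 * M_PI * x / g.Lx, ay = 2.0 * M_PI * y / g.Ly;
    cx += std::cos(ax); sx += std::sin(ax);
    cy += std::cos(ay); sy += std::sin(ay);
    sz += z;
  }
  double mx = std::atan2(sx, cx) / (2.0 * M_PI) * g.Lx;
  double my = std::atan2(sy, cy) / (2.0 * M_PI) * g.Ly;
  if (mx < 0) mx += g.Lx;
  if (my < 0) my += g.Ly;
  double mz = sz / sites.size();
  double nx = std::cos(az), ny = std::sin(az);
  std::vector<char> side(sites.size());
  int n_new = 0;
  for (size_t k = 0; k < sites.size(); ++k) {
    int i = sites[k];
    double dx = (i % g.Lx) - mx, dy = ((i / g.Lx) % g.Ly) - my;
    if (dx > g.Lx / 2.0) dx -= g.Lx; else if (dx < -g.Lx / 2.0) dx += g.Lx;
    if (dy > g.Ly / 2.0) dy -= g.Ly; else if (dy < -g.Ly / 2.0) dy += g.Ly;
    side[k] = (dx * nx + dy * ny >= 0.0) ? 1 : 0;
    n_new += side[k];
  }
  if (n_new == 0 || n_new == (int) sites.size()) {
    // degenerate plane (all sites one side): split by site order instead
    for (size_t k = 0; k < sites.size(); ++k) side[k] = (k < sites.size() / 2) ? 1 : 0;
    n_new = (int) (sites.size() / 2);
  }
  for (size_t k = 0; k < sites.size(); ++k)
    if (side[k]) grid[sites[k]] = new_id;
  r.n_kept = (int) sites.size() - n_new;
  r.n_new = n_new;
  r.cx = mx; r.cy = my; r.cz = mz;
  return r;
}

// [[Rcpp::export]]
List cpp_divide(IntegerVector grid, IntegerVector dims, int cell_id,
                int new_id, double azimuth) {
  Geom g; g.build(dims[0], dims[1], dims[2]);
  std::vector<int> gr(grid.begin(), grid.end());
  SplitResult r = split_cell(gr, g, cell_id, new_id, azimuth);
  IntegerVector out(gr.begin(), gr.end());
  out.attr("dim") = dims;
  return List::create(_["grid"] = out, _["n_kept"] = r.n_kept,
                      _["n_new"] = r.n_new,
                      _["centroid"] = NumericVector::create(r.cx, r.cy, r.cz));
}

// [[Rcpp::export]]
List cpp_audit(IntegerVector grid, IntegerVector dims, int n_cells) {
  Geom g; g.build(dims[0], dims[1], dims[2]);
  NumericVector vol(n_cells + 1), surf(n_cells + 1);
  std::vector<int> gr(grid.begin(), grid.end());
  for (int i = 0; i < g.N; ++i) vol[gr[i]] += 1.0;
  for (int i = 0; i < g.N; ++i) {
    int a = gr[i];
    if (a == 0) continue;
    const int *nb = &g.nbr[(size_t) i * 18];
    for (int k = 0; k < 6; ++k) {
      int j = nb[k];
      if (j < 0 || gr[j] != a) surf[a] += 1.0;
    }
  }
  return List::create(_["vol"] = vol, _["surf"] = surf);
}

// [[Rcpp::export]]
double cpp_delta_h(IntegerVector grid, NumericVector omega, IntegerVector dims,
                   IntegerVector cell_type, NumericVector cell_Vt,
                   NumericVector cell_Pt, NumericVector cell_t0,
                   IntegerVector cell_gen, NumericVector cell_next_div,
                   NumericMatrix J, double lambda_V, double lambda_P,
                   double mu, double temp, int rounding_sign,
                   double rounding_amp, double tau_tt, double tau_tm,
                   double rounding_window, double t_now,
                   int site, int src_site, int candidate_id) {
  Sim S;
  sim_init(S, grid, omega, dims, cell_type, cell_Vt, cell_Pt, cell_t0,
           cell_gen, cell_next_div, J, lambda_V, lambda_P, mu, temp,
           rounding_sign, rounding_amp, tau_tt, tau_tm, rounding_window);
  S.refresh_rounding(t_now);
  return S.delta_h(site - 1, src_site - 1, candidate_id);
}

// [[Rcpp::export]]
double cpp_total_h(IntegerVector grid, NumericVector omega, IntegerVector dims,
                   IntegerVector cell_type, NumericVector cell_Vt,
                   NumericVector cell_Pt, NumericVector cell_t0,
                   IntegerVector cell_gen, NumericVector cell_next_div,
                   NumericMatrix J, double lambda_V, double lambda_P,
                   double mu, double temp, int rounding_sign,
                   double rounding_amp, double tau_tt, double tau_tm,
                   double rounding_window, double t_now) {
  Sim S;
  sim_init(S, grid, omega, dims, cell_type, cell_Vt, cell_Pt, cell_t0,
           cell_gen, cell_next_div, J, lambda_V, lambda_P, mu, temp,
           rounding_sign, rounding_amp, tau_tt, tau_tm, rounding_window);
  S.refresh_rounding(t_now);
  return S.total_h();
}

// ---------------------------------------------------------------------------
// main driver: n_mcs sweeps of (copy attempts -> field step -> divisions)
// [[Rcpp::export]]
List cpp_run(IntegerVector grid, NumericVector omega, IntegerVector dims,
             IntegerVector cell_type, NumericVector cell_Vt,
             NumericVector cell_Pt, NumericVector cell_t0,
             IntegerVector cell_gen, NumericVector cell_next_div,
             NumericMatrix J, double lambda_V, double lambda_P,
             double mu, double temp, int rounding_sign, double rounding_amp,
             double tau_tt, double tau_tm, double rounding_window,
             bool field_enabled, double field_p, double field_d,
             double field_D, int n_substeps, double spacing,
             double cycle_mean, double cycle_sd,
             int n_mcs, double t_start, double seed,
             int track_every, int snapshot_every, bool do_divisions,
             int stop_after_events, double tumor_Vt, double tumor_Pt) {
  Sim S;
  sim_init(S, grid, omega, dims, cell_type, cell_Vt, cell_Pt, cell_t0,
           cell_gen, cell_next_div, J, lambda_V, lambda_P, mu, temp,
           rounding_sign, rounding_amp, tau_tt, tau_tm, rounding_window);
  Rng rng((uint64_t) seed);
  const int N = S.g.N;
  const int Lxy = S.g.Lx * S.g.Ly;

  // frozen-site mask (matrix cells + top plane); matrix never moves, so
  // this is fixed for the whole run
  std::vector<uint8_t> frozen(N, 0), blocked(N, 0);
  for (int i = 0; i < N; ++i) {
    int z = i / Lxy;
    bool mat = (S.type[S.grid[i]] == T_MATRIX);
    blocked[i] = mat;
    frozen[i] = mat || (z == S.g.Lz - 1);
  }

  std::vector<double> tracks;    // t, id, x, y, z, vol  (tumor cells)
  std::vector<double> events;    // t, parent, daughter, x, y, z
  std::vector<double> elog;      // t, H, acceptance rate
  List snapshots;
  std::vector<double> snap_times;
  int n_events = 0;

  auto draw_cycle = [&]() {
    if (cycle_sd <= 0) return cycle_mean;
    double v;
    do { v = cycle_mean + cycle_sd * rng.norm(); } while (v <= 0);
    return v;
  };

  auto log_tracks = [&](double t) {
    for (size_t c = 1; c < S.type.size(); ++c) {
      if (S.type[c] != T_TUMOR || S.vol[c] <= 0) continue;
      double sx = 0, cx = 0, sy = 0, cy = 0, sz = 0; int n = 0;
      for (int i = 0; i < N; ++i) {
        if (S.grid[i] != (int) c) continue;
        int x = i % S.g.Lx, y = (i / S.g.Lx) % S.g.Ly, z = i / Lxy;
        double ax = 2.0 * M_PI * x / S.g.Lx, ay = 2.0 * M_PI * y / S.g.Ly;
        cx += std::cos(ax); sx += std::sin(ax);
        cy += std::cos(ay); sy += std::sin(ay);
        sz += z; ++n;
      }
      double mx = std::atan2(sx, cx) / (2.0 * M_PI) * S.g.Lx;
      double my = std::atan2(sy, cy) / (2.0 * M_PI) * S.g.Ly;
      if (mx < 0) mx += S.g.Lx;
      if (my < 0) my += S.g.Ly;
      tracks.push_back(t); tracks.push_back((double) c);
      tracks.push_back(mx * spacing); tracks.push_back(my * spacing);
      tracks.push_back(sz / n * spacing); tracks.push_back(S.vol[c]);
    }
  };

  auto take_snapshot = [&](double t) {
    IntegerVector gsnap(S.grid.begin(), S.grid.end());
    gsnap.attr("dim") = dims;
    NumericVector osnap(S.omega.begin(), S.omega.end());
    osnap.attr("dim") = dims;
    snapshots.push_back(List::create(_["t"] = t, _["grid"] = gsnap,
                                     _["omega"] = osnap));
    snap_times.push_back(t);
  };

  double t = t_start;
  S.refresh_rounding(t);
  elog.push_back(t); elog.push_back(S.total_h()); elog.push_back(NA_REAL);
  log_tracks(t);
  if (snapshot_every > 0) take_snapshot(t);

  std::vector<uint8_t> produce(N, 0);
  int mcs_done = 0;
  for (int step = 0; step < n_mcs; ++step) {
    S.refresh_rounding(t);
    long accepted = 0;
    for (int a = 0; a < N; ++a) {
      int s = rng.below(N);
      if (frozen[s]) continue;
      int k = rng.below(18);
      int src = S.g.nbr[(size_t) s * 18 + k];
      if (src < 0) continue;
      int c = S.grid[src];
      int o = S.grid[s];
      if (c == o) continue;
      if (S.type[c] == T_MATRIX) continue;           // substrate never copies in
      if (o > 0 && S.vol[o] <= 1.0) continue;        // cells never vanish
      double dH = S.delta_h(s, src, c);
      bool acc = (dH <= 0.0) ||
                 (S.temp > 0.0 && rng.unif() < std::exp(-dH / S.temp));
      if (acc) { S.apply_copy(s, c); ++accepted; }
    }

    if (field_enabled) {
      for (int i = 0; i < N; ++i) produce[i] = (S.type[S.grid[i]] == T_CORE);
      field_substeps(S.omega, S.g, blocked, produce, field_p, field_d,
                     field_D, 1.0 / n_substeps, n_substeps, spacing);
    }

    t = t_start + (step + 1);
    ++mcs_done;

    if (do_divisions) {
      size_t ncell_before = S.type.size();
      for (size_t c = 1; c < ncell_before; ++c) {
        if (S.type[c] != T_TUMOR || S.next_div[c] > t) continue;
        if (S.vol[c] < 2.0) continue;  // deferred until it has >= 2 sites
        int new_id = (int) S.type.size();
        double az = rng.unif() * 2.0 * M_PI;
        SplitResult r = split_cell(S.grid, S.g, (int) c, new_id, az);
        if (r.n_new == 0) continue;
        S.type.push_back(T_TUMOR);
        S.gen.push_back(S.gen[c] + 1);
        S.gen[c] = S.gen[c] + 1;
        S.Vt.push_back(tumor_Vt); S.Pt.push_back(tumor_Pt);
        S.Vt[c] = tumor_Vt; S.Pt[c] = tumor_Pt;
        S.t0.push_back(t); S.t0[c] = t;
        S.next_div.push_back(t + draw_cycle());
        S.next_div[c] = t + draw_cycle();
        S.vol.push_back(0.0); S.surf.push_back(0.0);
        S.rf_tt.push_back(0.0); S.rf_tm.push_back(0.0);
        // local recount for the two daughters
        S.vol[c] = r.n_kept; S.vol[new_id] = r.n_new;
        double s_old = 0, s_new = 0;
        for (int i = 0; i < N; ++i) {
          int a = S.grid[i];
          if (a != (int) c && a != new_id) continue;
          const int *nb = &S.g.nbr[(size_t) i * 18];
          int exposed = 0;
          for (int kk = 0; kk < 6; ++kk) {
            int j = nb[kk];
            if (j < 0 || S.grid[j] != a) ++exposed;
          }
          if (a == (int) c) s_old += exposed; else s_new += exposed;
        }
        S.surf[c] = s_old; S.surf[new_id] = s_new;
        events.push_back(t); events.push_back((double) c);
        events.push_back((double) new_id);
        events.push_back(r.cx * spacing); events.push_back(r.cy * spacing);
        events.push_back(r.cz * spacing);
        ++n_events;
      }
    }

    bool at_log = (track_every > 0 && (step + 1) % track_every == 0);
    if (at_log) {
      S.refresh_rounding(t);
      elog.push_back(t); elog.push_back(S.total_h());
      elog.push_back((double) accepted / N);
      log_tracks(t);
    }
    if (snapshot_every > 0 && (step + 1) % snapshot_every == 0) take_snapshot(t);
    if (stop_after_events > 0 && n_events >= stop_after_events) break;
    if ((step & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  // package results back for R
  int ncell = (int) S.type.size() - 1;
  IntegerVector g_out(S.grid.begin(), S.grid.end());
  g_out.attr("dim") = dims;
  NumericVector o_out(S.omega.begin(), S.omega.end());
  o_out.attr("dim") = dims;
  IntegerVector ty(ncell), gn(ncell);
  NumericVector vt(ncell), pt(ncell), tz(ncell), nd(ncell), vl(ncell), sf(ncell);
  for (int c = 1; c <= ncell; ++c) {
    ty[c - 1] = S.type[c]; gn[c - 1] = S.gen[c];
    vt[c - 1] = S.Vt[c]; pt[c - 1] = S.Pt[c];
    tz[c - 1] = S.t0[c]; nd[c - 1] = S.next_div[c];
    vl[c - 1] = S.vol[c]; sf[c - 1] = S.surf[c];
  }
  int ntr = (int) tracks.size() / 6;
  NumericMatrix tr(ntr, 6);
  for (int i = 0; i < ntr; ++i)
    for (int j = 0; j < 6; ++j) tr(i, j) = tracks[(size_t) i * 6 + j];
  int nev = (int) events.size() / 6;
  NumericMatrix ev(nev, 6);
  for (int i = 0; i < nev; ++i)
    for (int j = 0; j < 6; ++j) ev(i, j) = events[(size_t) i * 6 + j];
  int nel = (int) elog.size() / 3;
  NumericMatrix el(nel, 3);
  for (int i = 0; i < nel; ++i)
    for (int j = 0; j < 3; ++j) el(i, j) = elog[(size_t) i * 3 + j];
  return List::create(
    _["grid"] = g_out, _["omega"] = o_out,
    _["cell_type"] = ty, _["cell_Vt"] = vt, _["cell_Pt"] = pt,
    _["cell_t0"] = tz, _["cell_gen"] = gn, _["cell_next_div"] = nd,
    _["cell_vol"] = vl, _["cell_surf"] = sf,
    _["tracks"] = tr, _["events"] = ev, _["energy"] = el,
    _["snapshots"] = snapshots, _["n_mcs"] = mcs_done, _["t_end"] = t);
}
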