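// Compiled sampling engine: Langevin propagation (BAOAB / overdamped
// Euler-Maruyama) of a point ligand on the toy potentials, with
// well-tempered hill deposition on one collective variable, funnel
// restraint walls, and a piecewise-linear moving restraint.
//
// Determinism contract: per-walker counter-based RNG streams (splitmix64 ->
// PCG32) keyed by (seed, walker id); hill heights computed by direct
// summation over prior hills truncated at 6 sigma, so an R-level replay of
// the ledger reproduces every stored height to round-off.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static const double KB = 0.0083145; // kJ/mol/K

// ---------------------------------------------------------------- RNG ----
struct PCG32 {
  uint64_t state, inc;
  double spare;
  bool has_spare;
  void seed(uint64_t initstate, uint64_t initseq) {
    state = 0u; inc = (initseq << 1u) | 1u;
    next(); state += initstate; next();
    has_spare = false; spare = 0.0;
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double uniform() { // in (0, 1]
    return (next() + 1.0) * (1.0 / 4294967296.0);
  }
  double normal() { // Box-Muller with cached spare
    if (has_spare) { has_spare = false; return spare; }
    double u1 = uniform(), u2 = uniform();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 2.0 * M_PI * u2;
    spare = r * std::sin(a); has_spare = true;
    return r * std::cos(a);
  }
};

static uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Counter-based stream normals, exposed for tests and for R-side use.
// [[Rcpp::export]]
NumericVector counter_rng_normal(int seed, int stream, int n) {
  PCG32 rng;
  uint64_t s = splitmix64(((uint64_t)(uint32_t)seed << 32) ^ (uint64_t)(uint32_t)stream);
  rng.seed(s, splitmix64(s ^ 0xDA442D24ULL));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.normal();
  return out;
}

// ------------------------------------------------------------ potential ---
struct Potential {
  int kind; // 1 double_well_1d, 2 funnel_pocket_3d, 3 harmonic
  double a, b;            // double well
  double D, s2, kfloor;   // pocket (s2 = sigma^2)
  double k;               // harmonic
  std::vector<double> center;
  int dim;
  void grad(const double* x, double* g) const {
    if (kind == 1) {
      g[0] = 4.0 * a * x[0] * (x[0] * x[0] - 1.0) + b;
    } else if (kind == 2) {
      double r2 = x[0] * x[0] + x[1] * x[1] + x[2] * x[2];
      double pref = (D / s2) * std::exp(-r2 / (2.0 * s2));
      g[0] = pref * x[0]; g[1] = pref * x[1]; g[2] = pref * x[2];
      if (x[2] < 0) g[2] += kfloor * x[2];
    } else {
      for (int j = 0; j < dim; ++j) g[j] = k * (x[j] - center[j]);
    }
  }
};

// --------------------------------------------------------- bias grid -----
struct BiasGrid {
  double lo, hi, h;
  int n;
  std::vector<double> V, V1, V2; // value, dV/ds, d2V/ds2 at nodes
  void init(double lo_, double hi_, double spacing) {
    lo = lo_; hi = hi_;
    n = (int)std::floor((hi - lo) / spacing) + 1;
    if (n < 2) n = 2;
    h = (hi - lo) / (n - 1);
    V.assign(n, 0.0); V1.assign(n, 0.0); V2.assign(n, 0.0);
  }
  void add_hill(double c, double sig, double height) {
    double s2 = sig * sig;
    int i0 = (int)std::ceil((c - 6.0 * sig - lo) / h) - 1; if (i0 < 0) i0 = 0;
    int i1 = (int)std::floor((c + 6.0 * sig - lo) / h) + 1; if (i1 > n - 1) i1 = n - 1;
    for (int i = i0; i <= i1; ++i) {
      double d = c - (lo + i * h);
      if (std::fabs(d / sig) > 6.0) continue; // same test as direct summation
      double g = height * std::exp(-d * d / (2.0 * s2));
      V[i] += g;
      V1[i] += g * d / s2;
      V2[i] += g * (d * d / s2 - 1.0) / s2;
    }
  }
  // quintic Hermite (f, f', f'' at both ends); mirrors the R grid_eval
  void eval(double s, double& val, double& der) const {
    if (s < lo) s = lo;
    if (s > hi) s = hi;
    int i = (int)std::floor((s - lo) / h);
    if (i > n - 2) i = n - 2;
    if (i < 0) i = 0;
    double t = (s - (lo + i * h)) / h;
    double t2 = t * t, t3 = t2 * t, t4 = t3 * t, t5 = t4 * t;
    double H00 = 1 - 10 * t3 + 15 * t4 - 6 * t5;
    double H10 = t - 6 * t3 + 8 * t4 - 3 * t5;
    double H20 = 0.5 * t2 - 1.5 * t3 + 1.5 * t4 - 0.5 * t5;
    double H01 = 10 * t3 - 15 * t4 + 6 * t5;
    double H11 = -4 * t3 + 7 * t4 - 3 * t5;
    double H21 = 0.5 * t3 - t4 + 0.5 * t5;
    double dH00 = -30 * t2 + 60 * t3 - 30 * t4;
    double dH10 = 1 - 18 * t2 + 32 * t3 - 15 * t4;
    double dH20 = t - 4.5 * t2 + 6 * t3 - 2.5 * t4;
    double dH01 = 30 * t2 - 60 * t3 + 30 * t4;
    double dH11 = -12 * t2 + 28 * t3 - 15 * t4;
    double dH21 = 1.5 * t2 - 4 * t3 + 2.5 * t4;
    double f0 = V[i], f1 = V[i + 1];
    double g0 = V1[i], g1 = V1[i + 1];
    double c0 = V2[i], c1 = V2[i + 1];
    val = H00 * f0 + H10 * h * g0 + H20 * h * h * c0 +
          H01 * f1 + H11 * h * g1 + H21 * h * h * c1;
    der = (dH00 * f0 + dH01 * f1) / h + dH10 * g0 + dH11 * g1 +
          h * (dH20 * c0 + dH21 * c1);
  }
};

// ---------------------------------------------------------------- main ---
// [[Rcpp::export]]
List metad_engine(NumericMatrix x0, int pot_kind, NumericVector pot_params,
                  std::string scheme, double dt, double friction,
                  double temperature, double mass, double n_steps_d,
                  int save_stride,
                  bool do_metad, double h0, double sigma_cv, int dep_stride,
                  double gamma, double grid_lo, double grid_hi,
                  double grid_spacing,
                  bool has_funnel, NumericVector funnel_params,
                  bool has_moving, NumericVector mr_times,
                  NumericVector mr_centers, NumericVector mr_kappas,
                  NumericMatrix static_hills, int seed, double t0) {
  const int W = x0.nrow();
  const int dim = x0.ncol();
  const long long n_steps = (long long)n_steps_d;

  Potential pot; pot.kind = pot_kind; pot.dim = dim;
  pot.center.assign(dim, 0.0);
  if (pot_kind == 1) { pot.a = pot_params[0]; pot.b = pot_params[1]; }
  else if (pot_kind == 2) {
    pot.D = pot_params[0];
    pot.s2 = pot_params[1] * pot_params[1];
    pot.kfloor = pot_params[2];
  } else {
    pot.k = pot_params[0];
    for (int j = 0; j < dim && j + 1 < pot_params.size(); ++j)
      pot.center[j] = pot_params[j + 1];
  }

  // funnel frame (also defines the CV axis for 3D systems)
  double anchor[3] = {0, 0, 0}, axis[3] = {0, 0, 1};
  double alpha = 0, z_cc = 0, R_cyl = 0, z_wall = 0, kw = 0, kf = 0, tana = 0;
  if (has_funnel) {
    for (int j = 0; j < 3; ++j) { anchor[j] = funnel_params[j]; axis[j] = funnel_params[3 + j]; }
    alpha = funnel_params[6]; z_cc = funnel_params[7]; R_cyl = funnel_params[8];
    z_wall = funnel_params[9]; kw = funnel_params[10]; kf = funnel_params[11];
    tana = std::tan(alpha);
  }

  BiasGrid grid;
  bool use_bias = do_metad || static_hills.nrow() > 0;
  if (use_bias) grid.init(grid_lo, grid_hi, grid_spacing);

  // hill list (static entries first, then deposited)
  std::vector<double> hc, hsig, hh;
  for (int i = 0; i < static_hills.nrow(); ++i) {
    hc.push_back(static_hills(i, 0));
    hsig.push_back(static_hills(i, 1));
    hh.push_back(static_hills(i, 2));
    grid.add_hill(static_hills(i, 0), static_hills(i, 1), static_hills(i, 2));
  }

  std::vector<double> dep_time, dep_center, dep_height;
  std::vector<int> dep_walker;

  // per-walker state
  std::vector<std::vector<double>> X(W, std::vector<double>(dim));
  std::vector<std::vector<double>> Vel(W, std::vector<double>(dim, 0.0));
  std::vector<std::vector<double>> Fc(W, std::vector<double>(dim, 0.0));
  std::vector<PCG32> rng(W);
  for (int w = 0; w < W; ++w) {
    for (int j = 0; j < dim; ++j) X[w][j] = x0(w, j);
    uint64_t s = splitmix64(((uint64_t)(uint32_t)seed << 32) ^ (uint64_t)(uint32_t)w);
    rng[w].seed(s, splitmix64(s ^ 0xDA442D24ULL));
  }

  const double kTm = KB * temperature;
  const double kBdT = (std::isfinite(gamma)) ? KB * (gamma - 1.0) * temperature : -1.0;
  const bool overdamped = (scheme == "overdamped");
  const double mob = dt / (mass * friction);
  const double c1 = std::exp(-friction * dt);
  const double sig_o = std::sqrt(2.0 * kTm * mob);
  const double sig_b = std::sqrt(kTm / mass * (1.0 - c1 * c1));

  long long n_save = (save_stride > 0) ? (n_steps / save_stride) : 0;
  NumericMatrix colvar(W * n_save, 4 + dim); // time, walker, cv, x.., bias
  long long row = 0;
  int n_clipped = 0;
  double max_disp = 0.0;

  // cv + total force at a walker's current position
  auto eval_cv = [&](const double* x) -> double {
    if (dim == 1) return x[0];
    double z = 0;
    for (int j = 0; j < 3; ++j) z += (x[j] - anchor[j]) * axis[j];
    return z;
  };
  auto eval_force = [&](int w, double tnow, double* f) {
    const double* x = X[w].data();
    double g[3];
    pot.grad(x, g);
    for (int j = 0; j < dim; ++j) f[j] = -g[j];
    double cv = eval_cv(x);
    if (use_bias) {
      double val, der;
      grid.eval(cv, val, der);
      if (dim == 1) f[0] -= der;
      else for (int j = 0; j < 3; ++j) f[j] -= der * axis[j];
    }
    if (has_moving) {
      int nt = mr_times.size();
      double ce, ka;
      if (tnow >= mr_times[nt - 1]) { ce = mr_centers[nt - 1]; ka = mr_kappas[nt - 1]; }
      else if (tnow <= mr_times[0]) { ce = mr_centers[0]; ka = mr_kappas[0]; }
      else {
        int i = 0;
        while (i + 1 < nt && mr_times[i + 1] <= tnow) ++i;
        double wgt = (tnow - mr_times[i]) / (mr_times[i + 1] - mr_times[i]);
        ce = mr_centers[i] + wgt * (mr_centers[i + 1] - mr_centers[i]);
        ka = mr_kappas[i] + wgt * (mr_kappas[i + 1] - mr_kappas[i]);
      }
      double fr = -ka * (cv - ce);
      if (dim == 1) f[0] += fr;
      else for (int j = 0; j < 3; ++j) f[j] += fr * axis[j];
    }
    if (has_funnel && dim == 3) {
      double rel[3], z = 0;
      for (int j = 0; j < 3; ++j) rel[j] = x[j] - anchor[j];
      for (int j = 0; j < 3; ++j) z += rel[j] * axis[j];
      double perp[3], d2 = 0;
      for (int j = 0; j < 3; ++j) { perp[j] = rel[j] - z * axis[j]; d2 += perp[j] * perp[j]; }
      double d = std::sqrt(d2);
      double R = (z <= z_cc) ? (z_cc - z) * tana + R_cyl : R_cyl;
      if (d > R) {
        double exc = d - R;
        double dRdz = (z <= z_cc) ? -tana : 0.0;
        for (int j = 0; j < 3; ++j)
          f[j] -= kf * exc * (perp[j] / d - dRdz * axis[j]);
      }
      if (z > z_wall) for (int j = 0; j < 3; ++j) f[j] -= kw * (z - z_wall) * axis[j];
      if (z < 0)      for (int j = 0; j < 3; ++j) f[j] -= kw * z * axis[j];
    }
  };

  // direct-summation bias at a point (6-sigma truncation) for deposition
  auto bias_direct = [&](double s) -> double {
    double V = 0;
    size_t nh = hh.size();
    for (size_t k = 0; k < nh; ++k) {
      double d = hc[k] - s;
      if (std::fabs(d) > 6.0 * hsig[k]) continue;
      V += hh[k] * std::exp(-d * d / (2.0 * hsig[k] * hsig[k]));
    }
    return V;
  };

  for (int w = 0; w < W; ++w) eval_force(w, t0, Fc[w].data());

  long long chunk = do_metad ? dep_stride : n_steps;
  if (chunk <= 0) chunk = n_steps;
  long long done = 0;
  while (done < n_steps) {
    long long todo = std::min(chunk, n_steps - done);
    for (int w = 0; w < W; ++w) {
      double tnow = t0 + done * dt;
      for (long long s = 0; s < todo; ++s) {
        long long step = done + s + 1;
        double xold[3];
        for (int j = 0; j < dim; ++j) xold[j] = X[w][j];
        if (overdamped) {
          eval_force(w, tnow, Fc[w].data());
          for (int j = 0; j < dim; ++j)
            X[w][j] += mob * Fc[w][j] + sig_o * rng[w].normal();
        } else {
          for (int j = 0; j < dim; ++j) {
            double v = Vel[w][j] + 0.5 * dt * Fc[w][j] / mass;
            double xx = X[w][j] + 0.5 * dt * v;
            v = c1 * v + sig_b * rng[w].normal();
            X[w][j] = xx + 0.5 * dt * v;
            Vel[w][j] = v;
          }
          eval_force(w, tnow + dt, Fc[w].data());
          for (int j = 0; j < dim; ++j)
            Vel[w][j] += 0.5 * dt * Fc[w][j] / mass;
        }
        tnow += dt;
        double dsp = 0;
        for (int j = 0; j < dim; ++j) dsp += (X[w][j] - xold[j]) * (X[w][j] - xold[j]);
        if (dsp > max_disp) max_disp = dsp;
        if (save_stride > 0 && step % save_stride == 0) {
          double cv = eval_cv(X[w].data());
          double bv = 0, bd = 0;
          if (use_bias) grid.eval(cv, bv, bd);
          colvar(row, 0) = tnow;
          colvar(row, 1) = w;
          colvar(row, 2) = cv;
          for (int j = 0; j < dim; ++j) colvar(row, 3 + j) = X[w][j];
          colvar(row, 3 + dim) = bv;
          ++row;
        }
        if (do_metad && step % dep_stride == 0) {
          double cv = eval_cv(X[w].data());
          if (cv < grid_lo) { cv = grid_lo; ++n_clipped; }
          if (cv > grid_hi) { cv = grid_hi; ++n_clipped; }
          double Vhere = bias_direct(cv);
          double height = (kBdT > 0) ? h0 * std::exp(-Vhere / kBdT) : h0;
          hc.push_back(cv); hsig.push_back(sigma_cv); hh.push_back(height);
          grid.add_hill(cv, sigma_cv, height);
          dep_time.push_back(tnow);
          dep_center.push_back(cv);
          dep_height.push_back(height);
          dep_walker.push_back(w);
        }
      }
    }
    done += todo;
  }

  int nd = (int)dep_time.size();
  NumericMatrix hills(nd, 5);
  for (int i = 0; i < nd; ++i) {
    hills(i, 0) = dep_time[i];
    hills(i, 1) = dep_center[i];
    hills(i, 2) = sigma_cv;
    hills(i, 3) = dep_height[i];
    hills(i, 4) = dep_walker[i];
  }
  NumericMatrix xfin(W, dim), vfin(W, dim);
  for (int w = 0; w < W; ++w)
    for (int j = 0; j < dim; ++j) { xfin(w, j) = X[w][j]; vfin(w, j) = Vel[w][j]; }

  List grid_out = R_NilValue;
  if (use_bias)
    grid_out = List::create(_["lo"] = grid.lo, _["hi"] = grid.hi,
                            _["spacing"] = grid.h,
                            _["V"] = NumericVector(grid.V.begin(), grid.V.end()),
                            _["V1"] = NumericVector(grid.V1.begin(), grid.V1.end()),
                            _["V2"] = NumericVector(grid.V2.begin(), grid.V2.end()));
  return List::create(_["colvar"] = colvar, _["hills"] = hills,
                      _["x_final"] = xfin, _["v_final"] = vfin,
                      _["n_clipped"] = n_clipped,
                      _["max_displacement"] = std::sqrt(max_disp),
                      _["grid"] = grid_out,
                      _["time_final"] = t0 + n_steps_d * dt);
}

// Direct-summation bias over an arbitrary-dimensional ledger, vectorised
// over evaluation points; used by reweighting on large ledgers.
// [[Rcpp::export]]
NumericVector bias_direct_sum(NumericMatrix s, NumericMatrix centers,
                              NumericMatrix sigmas, NumericVector heights) {
  int np = s.nrow(), nh = centers.nrow(), ncv = s.ncol();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double V = 0;
    for (int k = 0; k < nh; ++k) {
      double q = 0; bool skip = false;
      for (int j = 0; j < ncv; ++j) {
        double z = (centers(k, j) - s(p, j)) / sigmas(k, j);
        if (std::fabs(z) > 6.0) { skip = true; break; }
        q += z * z;
      }
      if (!skip) V += heights[k] * std::exp(-q / 2.0);
    }
    out[p] = V;
  }
  return out;
}

// Fast well-tempered replay of a ledger (reference oracle stays in R).
// [[Rcpp::export]]
NumericVector replay_heights_cpp(NumericMatrix centers, NumericMatrix sigmas,
                                 NumericVector gammas, double h0,
                                 double temperature) {
  int n = centers.nrow(), ncv = centers.ncol();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    double V = 0;
    for (int i = 0; i < k; ++i) {
      double q = 0; bool skip = false;
      for (int j = 0; j < ncv; ++j) {
        double z = (centers(i, j) - centers(k, j)) / sigmas(i, j);
        if (std::fabs(z) > 6.0) { skip = true; break; }
        q += z * z;
      }
      if (!skip) V += out[i] * std::exp(-q / 2.0);
    }
    double kBdT = std::isfinite(gammas[k]) ? KB * (gammas[k] - 1.0) * temperature : -1.0;
    out[k] = (kBdT > 0) ? h0 * std::exp(-V / kBdT) : h0;
  }
  return out;
}
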