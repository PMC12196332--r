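// One-dimensional Langevin engine on an analytic potential of mean force,
// with optional harmonic restraint (umbrella windows) and optional
// well-tempered metadynamics hill deposition.
//
// Units: nm, ps, kJ/mol, amu (so force/mass has units nm/ps^2).
// The integrator is the BAOAB splitting; random numbers come from R's RNG
// so that set.seed() at the R level makes runs exactly reproducible.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Potential {
  std::vector<double> center, depth, width2; // width2 = w^2
  double wall_left, wall_right, wall_k;

  double energy(double s) const {
    double v = 0.0;
    for (size_t k = 0; k < center.size(); ++k) {
      const double d = s - center[k];
      v -= depth[k] * std::exp(-0.5 * d * d / width2[k]);
    }
    if (s < wall_left)  { const double d = s - wall_left;  v += 0.5 * wall_k * d * d; }
    if (s > wall_right) { const double d = s - wall_right; v += 0.5 * wall_k * d * d; }
    return v;
  }
  double gradient(double s) const {
    double g = 0.0;
    for (size_t k = 0; k < center.size(); ++k) {
      const double d = s - center[k];
      g += depth[k] * (d / width2[k]) * std::exp(-0.5 * d * d / width2[k]);
    }
    if (s < wall_left)  g += wall_k * (s - wall_left);
    if (s > wall_right) g += wall_k * (s - wall_right);
    return g;
  }
};

// Piecewise-linear lookup of an accumulated bias and its gradient on a
// uniform grid (the same device PLUMED uses to keep hill sums O(1) per step).
struct BiasGrid {
  double s0, ds;
  std::vector<double> V, dV;
  bool active = false;

  void init(double smin, double smax, double spacing) {
    s0 = smin; ds = spacing;
    const int n = (int)std::ceil((smax - smin) / spacing) + 1;
    V.assign(n, 0.0); dV.assign(n, 0.0);
    active = true;
  }
  double value(double s) const {
    if (!active) return 0.0;
    double x = (s - s0) / ds;
    int i = (int)std::floor(x);
    if (i < 0) i = 0;
    if (i > (int)V.size() - 2) i = (int)V.size() - 2;
    const double f = x - i;
    return V[i] * (1.0 - f) + V[i + 1] * f;
  }
  double grad(double s) const {
    if (!active) return 0.0;
    double x = (s - s0) / ds;
    int i = (int)std::floor(x);
    if (i < 0) i = 0;
    if (i > (int)dV.size() - 2) i = (int)dV.size() - 2;
    const double f = x - i;
    return dV[i] * (1.0 - f) + dV[i + 1] * f;
  }
  void add_hill(double c, double h, double sigma) {
    const double cut = 6.0 * sigma;
    int i0 = (int)std::floor((c - cut - s0) / ds);
    int i1 = (int)std::ceil((c + cut - s0) / ds);
    if (i0 < 0) i0 = 0;
    if (i1 > (int)V.size() - 1) i1 = (int)V.size() - 1;
    const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
    for (int i = i0; i <= i1; ++i) {
      const double d = s0 + i * ds - c;
      const double e = h * std::exp(-d * d * inv2s2);
      V[i] += e;
      dV[i] += -d / (sigma * sigma) * e;
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".cpp_simulate")]]
List cpp_simulate(NumericVector centers, NumericVector depths, NumericVector widths,
                  double wall_left, double wall_right, double wall_k,
                  double s_min, double s_max,
                  double temperature, double kB, double friction, double mass, double dt,
                  double n_steps, double n_equil, int record_stride, double s0,
                  double restraint_k, double restraint_c,
                  double metad_gamma, double metad_omega0, double metad_sigma, int metad_pace,
                  double grid_ds,
                  NumericVector static_bias_V, NumericVector static_bias_dV) {
  Potential pot;
  for (int k = 0; k < centers.size(); ++k) {
    pot.center.push_back(centers[k]);
    pot.depth.push_back(depths[k]);
    pot.width2.push_back(widths[k] * widths[k]);
  }
  pot.wall_left = wall_left; pot.wall_right = wall_right; pot.wall_k = wall_k;

  const bool metad = metad_pace > 0 && metad_omega0 > 0.0;
  BiasGrid grid;
  if (metad || static_bias_V.size() > 0) {
    grid.init(s_min, s_max, grid_ds);
    if (static_bias_V.size() > 0) {
      if (static_bias_V.size() != (int)grid.V.size())
        stop("static bias grid has %d points, expected %d", (int)static_bias_V.size(), (int)grid.V.size());
      for (int i = 0; i < static_bias_V.size(); ++i) {
        grid.V[i] = static_bias_V[i];
        grid.dV[i] = static_bias_dV[i];
      }
    }
  }

  const double kT = kB * temperature;
  const double kdT = metad ? kB * (metad_gamma - 1.0) * temperature : 0.0; // kB * DeltaT
  const double c1 = std::exp(-friction * dt);
  const double c2 = (temperature > 0.0) ? std::sqrt((1.0 - c1 * c1) * kT / mass) : 0.0;

  const R_xlen_t total_steps = (R_xlen_t)(n_steps + n_equil);
  const R_xlen_t equil = (R_xlen_t)n_equil;
  const R_xlen_t n_rec = (R_xlen_t)(n_steps) / record_stride;

  NumericVector rec_t(n_rec), rec_s(n_rec), rec_f(n_rec), rec_b(n_rec);
  std::vector<double> h_time, h_center, h_height;

  RNGScope rng;
  double s = s0;
  double v = (temperature > 0.0) ? std::sqrt(kT / mass) * norm_rand() : 0.0;
  double force = -(pot.gradient(s) + grid.grad(s)) - restraint_k * (s - restraint_c);
  R_xlen_t i_rec = 0;

  for (R_xlen_t step = 1; step <= total_steps; ++step) {
    // BAOAB
    v += 0.5 * dt * force / mass;
    s += 0.5 * dt * v;
    v = c1 * v + c2 * norm_rand();
    s += 0.5 * dt * v;
    // reflective walls at the domain edges (safety net behind the half-harmonic walls)
    if (s < s_min) { s = 2.0 * s_min - s; v = -v; }
    if (s > s_max) { s = 2.0 * s_max - s; v = -v; }
    if (!std::isfinite(s))
      stop("integration instability: non-finite coordinate at step %g", (double)step);
    force = -(pot.gradient(s) + grid.grad(s)) - restraint_k * (s - restraint_c);
    v += 0.5 * dt * force / mass;

    const R_xlen_t prod = step - equil; // production step index (<= 0 during equilibration)
    if (prod <= 0) continue;

    const double t = prod * dt;
    if (metad && prod % metad_pace == 0) {
      const double h = metad_omega0 * std::exp(-grid.value(s) / kdT);
      grid.add_hill(s, h, metad_sigma);
      h_time.push_back(t); h_center.push_back(s); h_height.push_back(h);
      force = -(pot.gradient(s) + grid.grad(s)) - restraint_k * (s - restraint_c);
    }
    if (prod % record_stride == 0 && i_rec < n_rec) {
      rec_t[i_rec] = t;
      rec_s[i_rec] = s;
      // generalized force on the CV: -d(F + V_bias)/ds at the sampled point
      rec_f[i_rec] = -(pot.gradient(s) + grid.grad(s));
      rec_b[i_rec] = grid.value(s);
      ++i_rec;
    }
  }

  return List::create(_["time"] = rec_t, _["s"] = rec_s,
                      _["gen_force"] = rec_f, _["bias"] = rec_b,
                      _["hill_time"] = wrap(h_time),
                      _["hill_center"] = wrap(h_center),
                      _["hill_height"] = wrap(h_height));
}
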