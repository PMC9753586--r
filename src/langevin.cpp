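#include <Rcpp.h>
using namespace Rcpp;

// Underdamped Langevin dynamics (BAOAB splitting) for a single particle on a
// 1D sum-of-negative-Gaussians potential, optionally biased on the fly by
// well-tempered metadynamics acting on x.
//
// The metadynamics bias is accumulated on a regular grid spanning the declared
// domain (as PLUMED grids do): each deposited hill adds its Gaussian and its
// derivative to the grid, and the bias energy/force felt by the particle is
// linearly interpolated. Individual hills are also logged so the caller can
// reconstruct the exact BiasState and write a HILLS file.
//
// Uses R's RNG so a set.seed() on the R side makes runs bit-reproducible.

static inline double pot_energy(double x, const NumericVector &d,
                                const NumericVector &c, const NumericVector &w) {
  double u = 0.0;
  for (int i = 0; i < d.size(); ++i) {
    double dx = x - c[i];
    u -= d[i] * std::exp(-dx * dx / (2.0 * w[i] * w[i]));
  }
  return u;
}

static inline double pot_force(double x, const NumericVector &d,
                               const NumericVector &c, const NumericVector &w) {
  // F = -dU/dx
  double f = 0.0;
  for (int i = 0; i < d.size(); ++i) {
    double s2 = w[i] * w[i];
    double dx = x - c[i];
    f -= d[i] * dx / s2 * std::exp(-dx * dx / (2.0 * s2));
  }
  return f;
}

// [[Rcpp::export]]
List cpp_run_langevin(NumericVector depths, NumericVector centers,
                      NumericVector widths, double dom_lo, double dom_hi,
                      double wall_k, double temperature, double friction,
                      double dt, double x0, double v0, double n_steps_d,
                      int stride, bool metad, double initial_height,
                      double hill_width, double bias_factor,
                      int deposition_stride, int n_grid) {
  const long long n_steps = (long long)n_steps_d;
  const double c1 = std::exp(-friction * dt);
  const double c3 = std::sqrt(temperature * (1.0 - c1 * c1));
  const double dgx = (dom_hi - dom_lo) / (n_grid - 1);
  const double sig2 = hill_width * hill_width;

  NumericVector vbias(n_grid), dbias(n_grid); // bias and its derivative on grid

  // linear interpolation helpers over the bias grid
  auto interp = [&](const NumericVector &g, double x) -> double {
    if (x <= dom_lo) return g[0];
    if (x >= dom_hi) return g[n_grid - 1];
    double u = (x - dom_lo) / dgx;
    int i = (int)u;
    double f = u - i;
    return g[i] * (1.0 - f) + g[i + 1] * f;
  };

  auto wall_force = [&](double x, long long &hits) -> double {
    if (x < dom_lo) { hits++; return -wall_k * (x - dom_lo); }
    if (x > dom_hi) { hits++; return -wall_k * (x - dom_hi); }
    return 0.0;
  };

  long long n_keep = n_steps / stride;
  NumericVector xs(n_keep), vs(n_keep), ts(n_keep);
  std::vector<double> hill_t, hill_c, hill_h;

  double x = x0, v = v0;
  long long wall_hits = 0;
  double f = pot_force(x, depths, centers, widths);
  if (metad) f -= interp(dbias, x);
  long long dummy = 0;
  f += wall_force(x, dummy);
  wall_hits = 0;

  long long kept = 0;
  for (long long step = 1; step <= n_steps; ++step) {
    // B half kick
    v += 0.5 * dt * f;
    // A half drift
    x += 0.5 * dt * v;
    // O full friction + noise
    v = c1 * v + c3 * norm_rand();
    // A half drift
    x += 0.5 * dt * v;
    // B half kick with fresh force
    f = pot_force(x, depths, centers, widths);
    if (metad) f -= interp(dbias, x);
    f += wall_force(x, wall_hits);
    v += 0.5 * dt * f;

    if (metad && (step % deposition_stride == 0)) {
      double vb = interp(vbias, x);
      double h = initial_height *
                 std::exp(-vb / ((bias_factor - 1.0) * temperature));
      hill_t.push_back(step * dt);
      hill_c.push_back(x);
      hill_h.push_back(h);
      for (int i = 0; i < n_grid; ++i) {
        double gx = dom_lo + i * dgx;
        double dx = gx - x;
        double g = h * std::exp(-dx * dx / (2.0 * sig2));
        vbias[i] += g;
        dbias[i] += -dx / sig2 * g;
      }
      // force field changed under the particle; refresh cached force
      f = pot_force(x, depths, centers, widths) - interp(dbias, x);
      f += wall_force(x, dummy);
    }

    if (step % stride == 0) {
      xs[kept] = x;
      vs[kept] = v;
      ts[kept] = step * dt;
      ++kept;
    }
  }

  // final bias evaluated at the retained samples (grid-interpolated)
  NumericVector bias_final(n_keep);
  if (metad) {
    for (long long k = 0; k < n_keep; ++k) bias_final[k] = interp(vbias, xs[k]);
  }

  NumericVector grid(n_grid);
  for (int i = 0; i < n_grid; ++i) grid[i] = dom_lo + i * dgx;

  return List::create(
      _["x"] = xs, _["v"] = vs, _["time"] = ts, _["bias"] = bias_final,
      _["hill_times"] = hill_t, _["hill_centers"] = hill_c,
      _["hill_heights"] = hill_h, _["grid"] = grid, _["grid_bias"] = vbias,
      _["n_wall_hits"] = (double)wall_hits, _["x_final"] = x,
      _["v_final"] = v);
}
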