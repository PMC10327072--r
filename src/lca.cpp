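#include <Rcpp.h>
using namespace Rcpp;

// Decision boundary at time t. collapse_linear = false gives a * exp(-beta t),
// the default exponential collapse; linear collapse is floored just above 0 so
// the bound stays strictly positive.
static inline double bound_at(double t, double a, double beta,
                              bool collapse_linear) {
  if (collapse_linear) {
    double b = a - beta * t;
    return (b > 1e-12) ? b : 1e-12;
  }
  return a * std::exp(-beta * t);
}

// Euler-Maruyama first-passage simulation of the four-accumulator LCA:
//   dy_i = (-k y_i - k m sum_{j != i} y_j + g V_i) dt + c sqrt(dt) N(0,1)
// with per-step rectification y_i <- max(y_i, 0). A trial ends at the first
// step where any accumulator reaches the (collapsing) boundary; ties at the
// crossing step are broken by highest activation, then uniformly at random.
// Uses R's RNG so batches are reproducible under set.seed().
//
// values: one row of four inputs per trial. Returns rt/choice/omitted per
// trial plus the number of random tie-breaks that were needed.
// [[Rcpp::export]]
List lca_run_batch(NumericMatrix values, double k, double m, double g,
                   double c, double a, double beta, double dt, double t_max,
                   bool collapse_linear) {
  const int n = values.nrow();
  const int p = values.ncol();
  const int n_steps = (int)std::ceil(t_max / dt - 1e-9);
  NumericVector rt(n, NA_REAL);
  IntegerVector choice(n, NA_INTEGER);
  LogicalVector omitted(n, true);
  int n_tie = 0;
  const double sqdt = std::sqrt(dt);
  std::vector<double> y(p);

  for (int tr = 0; tr < n; ++tr) {
    std::fill(y.begin(), y.end(), 0.0);
    for (int s = 1; s <= n_steps; ++s) {
      const double t = s * dt;
      double sumy = 0.0;
      for (int j = 0; j < p; ++j) sumy += y[j];
      for (int j = 0; j < p; ++j) {
        double drift = (-k * y[j] - k * m * (sumy - y[j]) +
                        g * values(tr, j)) * dt;
        double ynew = y[j] + drift;
        if (c > 0.0) ynew += c * sqdt * norm_rand();
        y[j] = (ynew > 0.0) ? ynew : 0.0;
        if (ISNAN(y[j]))
          stop("accumulator activation became NaN at t=%f (trial %d)", t,
               tr + 1);
      }
      const double bnd = bound_at(t, a, beta, collapse_linear);
      // crossing set: all accumulators at/above the bound this step
      double best = -1.0;
      int winner = -1;
      int ties = 0;
      for (int j = 0; j < p; ++j) {
        if (y[j] >= bnd) {
          if (y[j] > best) {
            best = y[j];
            winner = j;
            ties = 1;
          } else if (y[j] == best) {
            ++ties;
            // reservoir-style uniform pick among exact ties
            if (unif_rand() < 1.0 / ties) winner = j;
          }
        }
      }
      if (winner >= 0) {
        if (ties > 1) ++n_tie;
        rt[tr] = t;
        choice[tr] = winner + 1;
        omitted[tr] = false;
        break;
      }
    }
  }
  return List::create(_["rt"] = rt, _["choice"] = choice,
                      _["omitted"] = omitted, _["n_tie"] = n_tie);
}

// Single-trial integration against a caller-supplied matrix of standard
// normal deviates (n_steps x n_options), returning the full trajectory.
// Sharing one noise matrix across calls gives common random numbers: with
// m = 0 the path of accumulator i depends only on column i, so changing the
// other options' inputs leaves it bitwise identical (race equivalence).
// [[Rcpp::export]]
List lca_run_trial_traj(NumericVector values, double k, double m, double g,
                        double c, double a, double beta, double dt,
                        double t_max, bool collapse_linear,
                        NumericMatrix noise) {
  const int p = values.size();
  const int n_steps = (int)std::ceil(t_max / dt - 1e-9);
  if (noise.nrow() < n_steps || noise.ncol() != p)
    stop("noise matrix must be at least %d x %d", n_steps, p);
  NumericMatrix traj(n_steps + 1, p);
  std::vector<double> y(p, 0.0);
  const double sqdt = std::sqrt(dt);
  double rt = NA_REAL;
  int choice = NA_INTEGER;
  bool omitted = true;
  int filled = n_steps;

  for (int s = 1; s <= n_steps; ++s) {
    const double t = s * dt;
    double sumy = 0.0;
    for (int j = 0; j < p; ++j) sumy += y[j];
    for (int j = 0; j < p; ++j) {
      double ynew = y[j] +
                    (-k * y[j] - k * m * (sumy - y[j]) + g * values[j]) * dt +
                    c * sqdt * noise(s - 1, j);
      y[j] = (ynew > 0.0) ? ynew : 0.0;
      traj(s, j) = y[j];
    }
    const double bnd = bound_at(t, a, beta, collapse_linear);
    double best = -1.0;
    int winner = -1;
    for (int j = 0; j < p; ++j) {
      if (y[j] >= bnd && y[j] > best) {
        best = y[j];
        winner = j;
      }
    }
    if (winner >= 0) {
      rt = t;
      choice = winner + 1;
      omitted = false;
      filled = s;
      break;
    }
  }
  return List::create(
      _["rt"] = rt, _["choice"] = choice, _["omitted"] = omitted,
      _["trajectory"] = traj(Range(0, filled), Range(0, p - 1)));
}
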