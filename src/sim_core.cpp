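#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Lower-boundary rule for the structure vector: any city whose updated share
// falls below x_m is reset to its previous share; the excess mass is removed
// uniformly from the remaining cities, never pushing one of them below x_m
// (cities cut down to the floor drop out of subsequent sweeps).
// Modifies x in place; returns the number of reset events. Throws if every
// city sits at the floor and mass still has to be removed.
static int enforce_floor_inplace(std::vector<double> &x,
                                 const std::vector<double> &xprev,
                                 double xm, int max_sweeps,
                                 bool proportional) {
  const int n = (int)x.size();
  std::vector<char> fixed(n, 0); // reset or floored: excluded from cuts
  int events = 0;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    bool any_reset = false;
    for (int i = 0; i < n; ++i) {
      if (!fixed[i] && x[i] < xm - 1e-15) {
        x[i] = xprev[i] > xm ? xprev[i] : xm; // floor may have risen past
                                              // the former size

        fixed[i] = 1;
        ++events;
        any_reset = true;
      }
    }
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += x[i];
    double excess = s - 1.0;
    if (!any_reset && std::abs(excess) <= 1e-13) return events;
    // remove the excess uniformly among cities that can still absorb cuts:
    // equal absolute amounts, or a common proportional factor (neutral in
    // log shares), never cutting a city below the floor
    int guard = 0;
    while (excess > 1e-15) {
      int nfree = 0;
      double sfree = 0.0;
      for (int i = 0; i < n; ++i)
        if (!fixed[i] && x[i] > xm + 1e-15) {
          ++nfree;
          sfree += x[i];
        }
      if (nfree == 0)
        stop("lower boundary infeasible: all cities at the floor");
      double cut = excess / nfree;          // absolute mode
      double f = 1.0 - excess / sfree;      // proportional mode
      for (int i = 0; i < n; ++i) {
        if (fixed[i] || x[i] <= xm + 1e-15) continue;
        double room = x[i] - xm;
        double want = proportional ? x[i] * (1.0 - f) : cut;
        double c = want < room ? want : room;
        x[i] -= c;
        excess -= c;
        if (c >= room - 1e-18) fixed[i] = 1; // hit the floor exactly
      }
      if (++guard > max_sweeps)
        stop("lower boundary enforcement did not converge");
    }
    if (excess < -1e-13) {
      // resets can only add mass; a negative excess here means xprev summed
      // below 1, which violates the preconditions
      stop("lower boundary enforcement produced a mass deficit");
    }
  }
  stop("lower boundary enforcement exceeded max sweeps");
}

// [[Rcpp::export]]
NumericVector enforce_floor_cpp(NumericVector x_new, NumericVector x_prev,
                                double x_m, int max_sweeps = 100,
                                bool proportional = false) {
  std::vector<double> x(x_new.begin(), x_new.end());
  std::vector<double> xp(x_prev.begin(), x_prev.end());
  enforce_floor_inplace(x, xp, x_m, max_sweeps, proportional);
  return wrap(x);
}

// One step of relative-growth noise: eps_i = eta_i - eta_bar - deltabar_i
// with eta_i ~ N(0, sigma_i), sigma_i = sigma * (n x_i)^(-alpha/2), and
// deltabar_i = sum_j delta_ij x_j for an antisymmetric delta(t) whose upper
// triangle has lognormal magnitudes and symmetric random signs.
static void draw_eps(std::vector<double> &eps, const std::vector<double> &x,
                     double sigma, double alpha, bool migration,
                     double mig_meanlog, double mig_sdlog) {
  const int n = (int)x.size();
  double eta_bar = 0.0;
  for (int i = 0; i < n; ++i) {
    double si = sigma;
    if (alpha != 0.0 && x[i] > 0.0)
      si = sigma * std::pow((double)n * x[i], -alpha / 2.0);
    eps[i] = ::norm_rand() * si;
    eta_bar += eps[i] * x[i];
  }
  for (int i = 0; i < n; ++i) eps[i] -= eta_bar;
  if (migration) {
    // accumulate deltabar without materializing the n x n matrix
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double mag = std::exp(mig_meanlog + mig_sdlog * ::norm_rand());
        double d = (::unif_rand() < 0.5) ? mag : -mag; // delta_ij
        eps[i] -= d * x[j];  // -deltabar_i contribution
        eps[j] += d * x[i];  // delta_ji = -delta_ij
      }
    }
  }
}

// [[Rcpp::export]]
List sim_structure_cpp(NumericVector x0, int T, int burn_in, double sigma,
                       double alpha, bool migration, double mig_meanlog,
                       double mig_sdlog, double x_m, bool enforce,
                       int record_every, double clip_floor,
                       bool floor_proportional, bool floor_dynamic) {
  const int n = x0.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> xnew(n), eps(n), sorted(n);
  std::vector<double> mean_sorted(n, 0.0), eps_sum(n, 0.0), eps_sq(n, 0.0);
  long clip_count = 0, floor_events = 0;
  int n_avg = 0;
  int n_rec = (record_every > 0) ? T / record_every : 0;
  NumericMatrix snapshots(n_rec, n);
  IntegerVector snap_times(n_rec);
  int rec = 0;

  GetRNGstate();
  for (int t = 1; t <= T; ++t) {
    draw_eps(eps, x, sigma, alpha, migration, mig_meanlog, mig_sdlog);
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      double w = 1.0 + eps[i];
      if (w < clip_floor) {
        w = clip_floor;
        ++clip_count;
      }
      xnew[i] = w * x[i];
      s += xnew[i];
    }
    for (int i = 0; i < n; ++i) xnew[i] /= s;
    if (enforce) {
      double xm_t = x_m;
      if (floor_dynamic) {
        double top = 0.0;
        for (int i = 0; i < n; ++i) if (x[i] > top) top = x[i];
        xm_t = top / n;
      }
      try {
        floor_events += enforce_floor_inplace(xnew, x, xm_t, 100,
                                              floor_proportional);
      } catch (...) {
        PutRNGstate();
        throw;
      }
    }
    x = xnew;
    for (int i = 0; i < n; ++i) {
      eps_sum[i] += eps[i];
      eps_sq[i] += eps[i] * eps[i];
    }
    if (t > burn_in) {
      sorted = x;
      std::sort(sorted.begin(), sorted.end(), std::greater<double>());
      for (int i = 0; i < n; ++i) mean_sorted[i] += sorted[i];
      ++n_avg;
    }
    if (record_every > 0 && t % record_every == 0 && rec < n_rec) {
      for (int i = 0; i < n; ++i) snapshots(rec, i) = x[i];
      snap_times[rec] = t;
      ++rec;
    }
  }
  PutRNGstate();

  if (n_avg > 0)
    for (int i = 0; i < n; ++i) mean_sorted[i] /= n_avg;
  NumericVector eps_mean(n), eps_sd(n);
  for (int i = 0; i < n; ++i) {
    eps_mean[i] = eps_sum[i] / T;
    double v = eps_sq[i] / T - eps_mean[i] * eps_mean[i];
    eps_sd[i] = v > 0 ? std::sqrt(v) : 0.0;
  }
  return List::create(
      _["x_final"] = wrap(x), _["mean_sorted"] = wrap(mean_sorted),
      _["snapshots"] = snapshots, _["snap_times"] = snap_times,
      _["eps_mean"] = eps_mean, _["eps_sd"] = eps_sd,
      _["n_averaged"] = n_avg, _["clip_count"] = (double)clip_count,
      _["floor_events"] = (double)floor_events);
}

// Free-running structure dynamics with an absorbing floor: records the first
// step at which each city's share drops below x_m (0 = not absorbed within
// max_T). No boundary enforcement; dynamics continues for the other cities.
// [[Rcpp::export]]
IntegerVector sim_first_passage_cpp(NumericVector x0, double sigma,
                                    double alpha, bool migration,
                                    double mig_meanlog, double mig_sdlog,
                                    double x_m, int max_T) {
  const int n = x0.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> eps(n);
  IntegerVector fp(n, 0);
  int remaining = n;
  GetRNGstate();
  for (int t = 1; t <= max_T && remaining > 0; ++t) {
    draw_eps(eps, x, sigma, alpha, migration, mig_meanlog, mig_sdlog);
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      double w = 1.0 + eps[i];
      if (w < 1e-3) w = 1e-3;
      x[i] *= w;
      s += x[i];
    }
    for (int i = 0; i < n; ++i) x[i] /= s;
    for (int i = 0; i < n; ++i) {
      if (fp[i] == 0 && x[i] < x_m) {
        fp[i] = t;
        --remaining;
      }
    }
  }
  PutRNGstate();
  return fp;
}
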