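#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// RNG stream discipline shared with the pure-R reference scheduler
// (R/engine-reference.R): bounded integer draws and Fisher-Yates
// permutations built on R's uniform generator, so both engines consume
// the stream identically and produce bit-identical trajectories.

static inline int draw_int(int n) {
  int j = (int)(unif_rand() * n);
  return j >= n ? n - 1 : j;  // unif_rand() < 1, guard against rounding
}

static void draw_perm(std::vector<int> &idx) {
  const int k = (int)idx.size();
  for (int i = k - 1; i >= 1; --i) {
    int j = draw_int(i + 1);
    std::swap(idx[i], idx[j]);
  }
}

// One generation of the four-phase scheduler:
//   Choose Food -> Eat -> Calculate Fitness -> Leave
// status: 0 searching, 1 feeding, 2 displaced (for the rest of the
// current iteration). Occupant lists per food use swap-removal; a
// winning challenger takes the loser's slot position, so opponent
// indexing stays identical between engines.
//
// truncated = true runs with no fixed generation length: after each
// fitness phase, individuals whose fitness first exceeds `cutoff` join
// an arrival list; the generation stops once the list reaches
// n_parents (same-iteration ties are pooled, then the list is randomly
// subsampled down to exactly n_parents).
// [[Rcpp::export]]
List engine_generation(NumericVector p0, NumericVector c0, NumericVector k,
                       NumericVector rails, double it_p, double it_c,
                       double init_dist, double cap, double eta,
                       double phi, double mu, int n_iter,
                       bool truncated, double cutoff, int n_parents,
                       int max_iter, IntegerVector group, int n_group,
                       bool record_series) {
  const int n = p0.size();
  const int nf = rails.size();
  const double half_pi = M_PI / 2.0;

  std::vector<double> x(p0.begin(), p0.end());
  std::vector<double> y(c0.begin(), c0.end());
  std::vector<double> K(k.begin(), k.end());
  std::vector<double> F(n), beta_sum(n, 0.0);
  std::vector<int> status(n, 0), food(n, -1), pos(n, -1);
  std::vector<int> feed_events(n, 0), displaced(n, 0);
  std::vector<int> c_init(n, 0), c_inv(n, 0), c_won(n, 0);
  std::vector<std::vector<int>> occ(nf);
  std::vector<bool> arrived(n, false);
  std::vector<int> arrivals;

  for (int i = 0; i < n; ++i) {
    double dx = it_p - x[i], dy = it_c - y[i];
    F[i] = std::exp(-mu * std::sqrt(dx * dx + dy * dy) / init_dist);
  }

  const int total_iter = truncated ? max_iter : n_iter;
  int iterations_run = 0;
  bool done = false;

  std::vector<double> ser_fit, ser_contests, ser_winrate;
  if (record_series && !truncated) {
    ser_fit.assign((size_t)n_iter * n_group, 0.0);
    ser_contests.assign((size_t)n_iter * n_group, 0.0);
    ser_winrate.assign((size_t)n_iter * n_group, NA_REAL);
  }

  std::vector<int> searchers, ord, batch;

  for (int it = 0; it < total_iter && !done; ++it) {
    // -- Choose Food: searchers, in a fresh random order, pick a food
    // uniformly; join if below capacity, otherwise contest a random
    // occupant. Losers are displaced for the rest of the iteration.
    searchers.clear();
    for (int i = 0; i < n; ++i)
      if (status[i] == 0) searchers.push_back(i);
    const int m = (int)searchers.size();
    if (m > 0) {
      ord.resize(m);
      for (int t = 0; t < m; ++t) ord[t] = t;
      draw_perm(ord);
      for (int t = 0; t < m; ++t) {
        const int s = searchers[ord[t]];
        const int f = draw_int(nf);
        if ((double)occ[f].size() < cap) {
          occ[f].push_back(s);
          pos[s] = (int)occ[f].size() - 1;
          food[s] = f;
          status[s] = 1;
        } else {
          const int oi = draw_int((int)occ[f].size());
          const int opp = occ[f][oi];
          const double q = 1.0 / (1.0 + std::exp(-eta * (F[s] - F[opp])));
          const double u = unif_rand();
          c_init[s]++; c_inv[s]++; c_inv[opp]++;
          if (u < q) {  // challenger takes the slot
            c_won[s]++;
            occ[f][oi] = s;
            pos[s] = oi;
            food[s] = f;
            status[s] = 1;
            status[opp] = 2;
            food[opp] = -1;
            pos[opp] = -1;
            displaced[opp]++;
          } else {
            c_won[opp]++;
            status[s] = 2;
            displaced[s]++;
          }
        }
      }
    }

    // -- Eat: feeding individuals move min(A, phi) along their rail;
    // beta is recorded at the pre-move state for every feed event,
    // including zero-movement events at the point of compromise.
    for (int i = 0; i < n; ++i) {
      if (status[i] != 1) continue;
      const double dx = it_p - x[i], dy = it_c - y[i];
      const double dist = std::sqrt(dx * dx + dy * dy);
      double beta = 0.0, A = 0.0;
      if (dist > 0.0) {
        beta = std::fabs(std::atan2(dy, dx) - rails[food[i]]);
        A = dist * std::cos(beta);
        if (A < 0.0) A = 0.0;
      }
      const double d = A < phi ? A : phi;
      x[i] += d * std::cos(rails[food[i]]);
      y[i] += d * std::sin(rails[food[i]]);
      beta_sum[i] += beta;
      feed_events[i]++;
    }

    // -- Calculate Fitness
    for (int i = 0; i < n; ++i) {
      const double dx = it_p - x[i], dy = it_c - y[i];
      F[i] = std::exp(-mu * std::sqrt(dx * dx + dy * dy) / init_dist);
    }

    if (record_series && !truncated) {
      std::vector<double> gfit(n_group, 0.0), gci(n_group, 0.0);
      std::vector<double> gwon(n_group, 0.0), ginv(n_group, 0.0);
      std::vector<int> gn(n_group, 0);
      for (int i = 0; i < n; ++i) {
        const int g = group[i];
        gfit[g] += F[i]; gci[g] += c_init[i];
        gwon[g] += c_won[i]; ginv[g] += c_inv[i];
        gn[g]++;
      }
      for (int g = 0; g < n_group; ++g) {
        ser_fit[(size_t)it * n_group + g] = gn[g] ? gfit[g] / gn[g] : NA_REAL;
        ser_contests[(size_t)it * n_group + g] = gn[g] ? gci[g] / gn[g] : NA_REAL;
        ser_winrate[(size_t)it * n_group + g] =
            ginv[g] > 0 ? gwon[g] / ginv[g] : NA_REAL;
      }
    }

    if (truncated) {
      batch.clear();
      for (int i = 0; i < n; ++i) {
        if (!arrived[i] && F[i] > cutoff) {
          arrived[i] = true;
          batch.push_back(i);
        }
      }
      if (!batch.empty()) {
        arrivals.insert(arrivals.end(), batch.begin(), batch.end());
        if ((int)arrivals.size() >= n_parents) {
          if ((int)arrivals.size() > n_parents) {
            draw_perm(arrivals);  // pooled random subsample of ties
            arrivals.resize(n_parents);
          }
          iterations_run = it + 1;
          done = true;
          continue;  // generation ends after this fitness phase
        }
      }
    }

    // -- Leave: displaced individuals resume searching; feeding
    // individuals leave spontaneously with probability P_leave
    // evaluated at the post-move state. Draws in agent-index order.
    for (int i = 0; i < n; ++i) {
      if (status[i] == 2) {
        status[i] = 0;
      } else if (status[i] == 1) {
        const double dx = it_p - x[i], dy = it_c - y[i];
        const double dist = std::sqrt(dx * dx + dy * dy);
        double beta = 0.0, A = 0.0;
        if (dist > 0.0) {
          beta = std::fabs(std::atan2(dy, dx) - rails[food[i]]);
          A = dist * std::cos(beta);
          if (A < 0.0) A = 0.0;
        }
        double pl = (1.0 - K[i]) * beta / half_pi +
                    std::max(0.0, (K[i] * phi - A) / phi);
        if (pl > 1.0) pl = 1.0;
        if (pl < 0.0) pl = 0.0;
        const double u = unif_rand();
        if (u < pl) {
          const int f = food[i];
          const int pi_ = pos[i];
          const int last = (int)occ[f].size() - 1;
          if (pi_ != last) {
            occ[f][pi_] = occ[f][last];
            pos[occ[f][pi_]] = pi_;
          }
          occ[f].pop_back();
          status[i] = 0;
          food[i] = -1;
          pos[i] = -1;
        }
      }
    }
    iterations_run = it + 1;
  }

  IntegerVector arr(arrivals.size());
  for (size_t i = 0; i < arrivals.size(); ++i) arr[i] = arrivals[i] + 1;

  List out = List::create(
      _["p"] = NumericVector(x.begin(), x.end()),
      _["c"] = NumericVector(y.begin(), y.end()),
      _["fitness"] = NumericVector(F.begin(), F.end()),
      _["feed_events"] = IntegerVector(feed_events.begin(), feed_events.end()),
      _["beta_sum"] = NumericVector(beta_sum.begin(), beta_sum.end()),
      _["iterations_displaced"] = IntegerVector(displaced.begin(), displaced.end()),
      _["contests_initiated"] = IntegerVector(c_init.begin(), c_init.end()),
      _["contests_involved"] = IntegerVector(c_inv.begin(), c_inv.end()),
      _["contests_won"] = IntegerVector(c_won.begin(), c_won.end()),
      _["n_iterations"] = iterations_run,
      _["arrivals"] = arr,
      _["aborted"] = truncated && !done);

  if (record_series && !truncated) {
    out["series_fitness"] =
        NumericMatrix(n_group, n_iter, ser_fit.begin());
    out["series_contests"] =
        NumericMatrix(n_group, n_iter, ser_contests.begin());
    out["series_winrate"] =
        NumericMatrix(n_group, n_iter, ser_winrate.begin());
  }
  return out;
}
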