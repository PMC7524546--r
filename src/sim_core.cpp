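#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <climits>
using namespace Rcpp;

// Forward Wright-Fisher + LGT engine. One call runs a whole replicate.
//
// The RNG is R's own (unif_rand / R::rpois), and every draw happens in the
// same order as the R-level reference steps (selection_step, mutation_step,
// lgt_step), so that for a fixed seed the two engines produce bit-identical
// trajectories. Fitness is accumulated column-by-column in plain double
// precision for the same reason (see src/Makevars).
//
// Event orders:
//   methods  : fitness -> selection -> mutation -> LGT (donors = parents'
//              final genomes); statistics on the offspring, after LGT.
//   figure1  : LGT (donors = previous generation's end-of-life genomes) ->
//              statistics (after recombination) -> mutation -> selection.
//
// In both orders the statistics point is after recombination, where a
// positive per-locus minimum is irreversible.

static void fitness_pass(const std::vector<int> &m, int N, int g,
                         const std::vector<double> &coef, bool multiplicative,
                         std::vector<double> &w) {
  std::fill(w.begin(), w.end(), 0.0);
  for (int i = 0; i < g; ++i) {
    const double ci = coef[i];
    const int *col = &m[(size_t)i * N];
    for (int j = 0; j < N; ++j) {
      double p = col[j] * ci;
      w[j] = w[j] + p;
    }
  }
  if (multiplicative) {
    for (int j = 0; j < N; ++j) w[j] = std::exp(w[j]);
  } else {
    for (int j = 0; j < N; ++j) {
      double v = 1.0 - w[j];
      w[j] = v > 0.0 ? v : 0.0;
    }
  }
}

// Wright-Fisher resampling by inversion of the cumulative fitness profile.
// Returns false when total fitness is zero (population extinct).
static bool selection_pass(const std::vector<int> &cur, std::vector<int> &nxt,
                           int N, int g, const std::vector<double> &w,
                           std::vector<double> &cw, std::vector<double> &u,
                           std::vector<int> &parents) {
  long double acc = 0.0L; // R's cumsum uses a long-double accumulator
  for (int j = 0; j < N; ++j) {
    acc += w[j];
    cw[j] = (double)acc;
  }
  const double tot = cw[N - 1];
  if (!(tot > 0.0)) return false;
  for (int j = 0; j < N; ++j) u[j] = unif_rand();
  for (int j = 0; j < N; ++j) {
    double x = u[j] * tot;
    int k = (int)(std::lower_bound(cw.begin(), cw.end(), x) - cw.begin());
    if (k >= N) k = N - 1;
    parents[j] = k;
  }
  for (int i = 0; i < g; ++i) {
    const int *src = &cur[(size_t)i * N];
    int *dst = &nxt[(size_t)i * N];
    for (int j = 0; j < N; ++j) dst[j] = src[parents[j]];
  }
  return true;
}

static void mutation_pass(std::vector<int> &m, int N, int g, double U,
                          std::vector<int> &nm) {
  for (int j = 0; j < N; ++j) nm[j] = (int)R::rpois(U);
  for (int j = 0; j < N; ++j) {
    for (int k = 0; k < nm[j]; ++k) {
      int locus = (int)(unif_rand() * g);
      if (locus >= g) locus = g - 1;
      m[j + (size_t)locus * N] += 1;
    }
  }
}

static void lgt_pass(std::vector<int> &m, const std::vector<int> &pool,
                     int N, int g, double lambda, int L,
                     std::vector<double> &u) {
  if (lambda <= 0.0) return;
  for (int j = 0; j < N; ++j) u[j] = unif_rand();
  for (int j = 0; j < N; ++j) {
    if (u[j] < lambda) {
      double ud = unif_rand();
      int donor = (int)(ud * N);
      if (donor >= N) donor = N - 1;
      double us = unif_rand();
      int start = (int)(us * g);
      if (start >= g) start = g - 1;
      for (int k = 0; k < L; ++k) {
        int col = start + k;
        if (col >= g) col -= g;
        m[j + (size_t)col * N] = pool[donor + (size_t)col * N];
      }
    }
  }
}

// LLC size, mean load, column minima (skipped when the LLC is non-empty, in
// which case all minima are provably zero), and — fused into the same memory
// traversal — the per-individual weighted mutation sums that give the next
// generation's fitness, accumulated in the exact column order of the R
// reference.
static void stats_pass(const std::vector<int> &m, int N, int g,
                       const std::vector<double> &coef,
                       std::vector<long long> &load, std::vector<double> &acc,
                       std::vector<int> &minima, int &llc, double &mean_load,
                       long long &fixed_total) {
  std::fill(load.begin(), load.end(), 0LL);
  std::fill(acc.begin(), acc.end(), 0.0);
  for (int i = 0; i < g; ++i) {
    const double ci = coef[i];
    const int *col = &m[(size_t)i * N];
    for (int j = 0; j < N; ++j) {
      load[j] += col[j];
      double p = col[j] * ci;
      acc[j] = acc[j] + p;
    }
  }
  llc = 0;
  long long tot = 0;
  for (int j = 0; j < N; ++j) {
    tot += load[j];
    if (load[j] == 0) ++llc;
  }
  mean_load = (double)tot / N;
  if (llc > 0) {
    std::fill(minima.begin(), minima.end(), 0);
    fixed_total = 0;
    return;
  }
  fixed_total = 0;
  for (int i = 0; i < g; ++i) {
    const int *col = &m[(size_t)i * N];
    int mn = INT_MAX;
    for (int j = 0; j < N; ++j) {
      if (col[j] < mn) {
        mn = col[j];
        if (mn == 0) break; // counts are non-negative: the minimum is 0
      }
    }
    minima[i] = mn;
    fixed_total += mn;
  }
}

static void acc_to_fitness(const std::vector<double> &acc, int N,
                           bool multiplicative, std::vector<double> &w) {
  if (multiplicative) {
    for (int j = 0; j < N; ++j) w[j] = std::exp(acc[j]);
  } else {
    for (int j = 0; j < N; ++j) {
      double v = 1.0 - acc[j];
      w[j] = v > 0.0 ? v : 0.0;
    }
  }
}

// [[Rcpp::export]]
List wf_run_cpp(IntegerMatrix counts0, NumericVector s, bool multiplicative,
                double U, double lambda, int L, int generations,
                bool stop_at_fixation, bool figure1_order) {
  const int N = counts0.nrow(), g = counts0.ncol();
  if ((int)s.size() != g) stop("length(s) must equal g");
  if (L < 1 || L > g) stop("L must lie in [1, g]");

  std::vector<int> cur(counts0.begin(), counts0.end());
  std::vector<int> nxt(cur.size());
  std::vector<int> pool;
  if (figure1_order) pool = cur;

  std::vector<double> coef(g);
  for (int i = 0; i < g; ++i)
    coef[i] = multiplicative ? log1p(-s[i]) : s[i];

  std::vector<double> w(N), cw(N), u(N), acc(N, 0.0);
  std::vector<int> parents(N), nm(N), minima(g);
  std::vector<long long> load(N);
  // weighted mutation sums of the (possibly non-zero) initial state
  for (int i = 0; i < g; ++i) {
    const double ci = coef[i];
    const int *col = &cur[(size_t)i * N];
    for (int j = 0; j < N; ++j) {
      double p = col[j] * ci;
      acc[j] = acc[j] + p;
    }
  }

  std::vector<int> llc_trace(generations), fixed_trace(generations);
  std::vector<double> load_trace(generations);
  IntegerVector first_fix(g, NA_INTEGER);
  int text = NA_INTEGER;
  bool extinct = false;
  int t_done = 0;

  int llc;
  double mean_load;
  long long fixed_total;

  for (int t = 1; t <= generations; ++t) {
    if (figure1_order) {
      lgt_pass(cur, pool, N, g, lambda, L, u);
      stats_pass(cur, N, g, coef, load, acc, minima, llc, mean_load,
                 fixed_total);
    } else {
      acc_to_fitness(acc, N, multiplicative, w);
      if (!selection_pass(cur, nxt, N, g, w, cw, u, parents)) {
        extinct = true;
        break;
      }
      mutation_pass(nxt, N, g, U, nm);
      lgt_pass(nxt, cur, N, g, lambda, L, u);
      stats_pass(nxt, N, g, coef, load, acc, minima, llc, mean_load,
                 fixed_total);
      std::swap(cur, nxt);
    }

    llc_trace[t - 1] = llc;
    load_trace[t - 1] = mean_load;
    fixed_trace[t - 1] = (int)fixed_total;
    if (llc == 0) {
      for (int i = 0; i < g; ++i) {
        if (minima[i] >= 1 && first_fix[i] == NA_INTEGER) {
          first_fix[i] = t;
          if (text == NA_INTEGER) text = t;
        }
      }
    }
    t_done = t;
    bool last = (stop_at_fixation && text != NA_INTEGER) || t == generations;

    if (figure1_order && !last) {
      mutation_pass(cur, N, g, U, nm);
      pool = cur; // end-of-life genomes feed the next generation's eDNA
      fitness_pass(cur, N, g, coef, multiplicative, w);
      if (!selection_pass(cur, nxt, N, g, w, cw, u, parents)) {
        extinct = true;
        break;
      }
      std::swap(cur, nxt);
    }
    if (last) break;
  }

  // per-locus minima at the last statistics point (stats_pass leaves them
  // in `minima`; all-zero whenever the LLC was non-empty)
  IntegerVector fixed_final(g);
  if (t_done > 0)
    for (int i = 0; i < g; ++i) fixed_final[i] = minima[i];

  IntegerMatrix final_counts(N, g);
  std::copy(cur.begin(), cur.end(), final_counts.begin());

  return List::create(
      _["llc_size"] = IntegerVector(llc_trace.begin(), llc_trace.begin() + t_done),
      _["mean_load"] = NumericVector(load_trace.begin(), load_trace.begin() + t_done),
      _["fixed_total"] = IntegerVector(fixed_trace.begin(), fixed_trace.begin() + t_done),
      _["first_fixation_generation"] = first_fix,
      _["fixed_mutation_count"] = fixed_final,
      _["text"] = text == NA_INTEGER ? IntegerVector::create(NA_INTEGER)
                                     : IntegerVector::create(text),
      _["extinct"] = extinct, _["generations_run"] = t_done,
      _["final_counts"] = final_counts);
}
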