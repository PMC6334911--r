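#include <Rcpp.h>
using namespace Rcpp;

// Weight feasibility: box [lo, hi] per coordinate, sum in [slo, shi].
// Repair = clip, then rescale multiplicatively onto the nearest violated sum
// bound and re-clip, iterated to a fixed point (<= 10 rounds).  The all-zero
// vector maps to the uniform vector at the lower sum bound.
static void repair_inplace(std::vector<double> &w,
                           const double lo, const double hi,
                           const double slo, const double shi) {
  const int M = (int)w.size();
  double s = 0.0;
  for (int j = 0; j < M; ++j) {
    if (w[j] < lo) w[j] = lo;
    if (w[j] > hi) w[j] = hi;
    s += w[j];
  }
  if (s == 0.0) {
    for (int j = 0; j < M; ++j) w[j] = slo / M;
    return;
  }
  for (int iter = 0; iter < 10; ++iter) {
    if (s >= slo - 1e-12 && s <= shi + 1e-12) break;
    const double target = (s < slo) ? slo : shi;
    const double scale = target / s;
    s = 0.0;
    for (int j = 0; j < M; ++j) {
      w[j] *= scale;
      if (w[j] < lo) w[j] = lo;
      if (w[j] > hi) w[j] = hi;
      s += w[j];
    }
  }
}

static void assert_feasible(const std::vector<double> &w,
                            const double lo, const double hi,
                            const double slo, const double shi) {
  double s = 0.0;
  for (size_t j = 0; j < w.size(); ++j) {
    if (w[j] < lo - 1e-9 || w[j] > hi + 1e-9)
      stop("internal error: infeasible weight coordinate evaluated");
    s += w[j];
  }
  if (s < slo - 1e-9 || s > shi + 1e-9)
    stop("internal error: weight vector with infeasible sum evaluated");
}

// Ordinal squared-distance fitness of one weight vector on a flattened panel.
// P is M x (n*K), column index (i*K + k); ac holds 0-based true grades.
// The determined class is the argmax of the weighted score with ties broken
// toward the lowest class index.
static double eval_one(const double *w, const double *Pdata,
                       const int M, const int n,
                       const int *ac, const int K) {
  double f = 0.0;
  const double *block = Pdata;
  for (int i = 0; i < n; ++i) {
    int dc = 0;
    double best = -1.0;
    for (int k = 0; k < K; ++k, block += M) {
      double s = 0.0;
      for (int j = 0; j < M; ++j) s += w[j] * block[j];
      if (s > best) { best = s; dc = k; }
    }
    const double d = (double)(dc - ac[i]);
    f += d * d;
  }
  return f;
}

// [[Rcpp::export]]
NumericVector de_eval_population(NumericMatrix W, NumericMatrix P,
                                 IntegerVector ac, int K) {
  const int np = W.nrow();
  const int M = W.ncol();
  if (P.nrow() != M) stop("weight width does not match panel classifier count");
  if (P.ncol() % K != 0 || P.ncol() / K != ac.size())
    stop("panel / label dimensions inconsistent");
  const int n = P.ncol() / K;
  const double *Pdata = P.begin();
  const int *acp = ac.begin();
  NumericVector out(np);
  std::vector<double> w(M);
  for (int m = 0; m < np; ++m) {
    for (int j = 0; j < M; ++j) w[j] = W(m, j);
    out[m] = eval_one(w.data(), Pdata, M, n, acp, K);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_repair_weights(NumericVector w_raw, double lo, double hi,
                                 double slo, double shi) {
  std::vector<double> w(w_raw.begin(), w_raw.end());
  repair_inplace(w, lo, hi, slo, shi);
  return NumericVector(w.begin(), w.end());
}

static inline int rand_index(const int n) {
  int r = (int)(unif_rand() * n);
  return (r >= n) ? n - 1 : r;
}

// DE/rand/1/bin minimization of the ordinal squared-distance fitness.
// Generational model: each trial vector competes with its parent and the
// winner enters the next generation (ties keep the parent).  Every trial
// vector is repaired onto the feasible region before evaluation.  Stops at
// max_iter generations, or earlier once the best fitness has been unchanged
// for `window` generations while the population fitness spread is below
// `tol`.  Uses R's RNG, so runs are reproducible under set.seed().
// [[Rcpp::export]]
List de_run(NumericMatrix P, IntegerVector ac, int K, int M,
            int np, int max_iter, double CR, double Fw,
            double lo, double hi, double slo, double shi,
            double tol, int window) {
  if (np < 4) stop("population size must be at least 4");
  if (P.nrow() != M) stop("panel classifier count mismatch");
  if (P.ncol() % K != 0 || P.ncol() / K != ac.size())
    stop("panel / label dimensions inconsistent");

  const int n = P.ncol() / K;
  const double *Pdata = P.begin();
  const int *acp = ac.begin();
  NumericMatrix pop(np, M), next(np, M);
  NumericVector fit(np);
  std::vector<double> w(M), trial(M);

  for (int m = 0; m < np; ++m) {
    for (int j = 0; j < M; ++j) w[j] = lo + unif_rand() * (hi - lo);
    repair_inplace(w, lo, hi, slo, shi);
    assert_feasible(w, lo, hi, slo, shi);
    for (int j = 0; j < M; ++j) pop(m, j) = w[j];
    fit[m] = eval_one(w.data(), Pdata, M, n, acp, K);
  }

  int best_idx = 0;
  for (int m = 1; m < np; ++m) if (fit[m] < fit[best_idx]) best_idx = m;
  double best_f = fit[best_idx];
  std::vector<double> best_w(M);
  for (int j = 0; j < M; ++j) best_w[j] = pop(best_idx, j);

  std::vector<double> history;
  history.reserve(max_iter);
  int stalled = 0;
  int gen = 0;

  for (gen = 1; gen <= max_iter; ++gen) {
    for (int m = 0; m < np; ++m) {
      int r1, r2, r3;
      do { r1 = rand_index(np); } while (r1 == m);
      do { r2 = rand_index(np); } while (r2 == m || r2 == r1);
      do { r3 = rand_index(np); } while (r3 == m || r3 == r1 || r3 == r2);
      const int jrand = rand_index(M);
      for (int j = 0; j < M; ++j) {
        if (unif_rand() < CR || j == jrand)
          trial[j] = pop(r1, j) + Fw * (pop(r2, j) - pop(r3, j));
        else
          trial[j] = pop(m, j);
      }
      repair_inplace(trial, lo, hi, slo, shi);
      assert_feasible(trial, lo, hi, slo, shi);
      const double ft = eval_one(trial.data(), Pdata, M, n, acp, K);
      if (ft < fit[m]) {
        for (int j = 0; j < M; ++j) next(m, j) = trial[j];
        fit[m] = ft;
      } else {
        for (int j = 0; j < M; ++j) next(m, j) = pop(m, j);
      }
    }
    std::swap(pop, next);

    int bi = 0;
    for (int m = 1; m < np; ++m) if (fit[m] < fit[bi]) bi = m;
    if (fit[bi] < best_f) {
      best_f = fit[bi];
      for (int j = 0; j < M; ++j) best_w[j] = pop(bi, j);
      stalled = 0;
    } else {
      ++stalled;
    }
    history.push_back(best_f);

    double fmin = fit[0], fmax = fit[0];
    for (int m = 1; m < np; ++m) {
      if (fit[m] < fmin) fmin = fit[m];
      if (fit[m] > fmax) fmax = fit[m];
    }
    if (stalled >= window && (fmax - fmin) < tol) break;
  }
  if (gen > max_iter) gen = max_iter;

  return List::create(
      _["best_weights"] = NumericVector(best_w.begin(), best_w.end()),
      _["best_fitness"] = best_f,
      _["generations"] = gen,
      _["history"] = NumericVector(history.begin(), history.end()),
      _["population"] = pop,
      _["pop_fitness"] = fit);
}
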