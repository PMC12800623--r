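#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Z-score event-based model internals.
//
// Conventions shared with the R side:
//  * events are 0-based ids 0..N-1; `bio[e]` is the 0-based biomarker of event
//    e and `zval[e]` its severity threshold (e.g. 1, 2, 3);
//  * a sequence is an integer vector of length N holding event ids in order
//    (element p = event occupying position p+1);
//  * stages run 0..N (N+1 values); severities are z = -w, missing entries NaN;
//  * validity: events of one biomarker appear in increasing threshold order.

static const double LOG_2PI = 1.8378770664093454836;

// piecewise-linear expected severity for each biomarker at each stage:
// control points (0,0), (p_j, z_j) for the biomarker's events at positions
// p_j (1-based), and (N, z_max) when the last event sits before position N.
static void build_trajectory(const std::vector<int> &seq,
                             const IntegerVector &bio,
                             const NumericVector &zval,
                             int n_bio, double z_max,
                             std::vector<double> &G /* (N+1) x n_bio, col-major */) {
  const int N = seq.size();
  // positions (1-based) and z values per biomarker, in position order
  std::vector<std::vector<std::pair<double, double> > > pts(n_bio);
  for (int b = 0; b < n_bio; ++b) {
    pts[b].clear();
    pts[b].push_back(std::make_pair(0.0, 0.0));
  }
  for (int p = 0; p < N; ++p) {
    int e = seq[p];
    pts[bio[e]].push_back(std::make_pair(double(p + 1), zval[e]));
  }
  for (int b = 0; b < n_bio; ++b) {
    if (pts[b].back().first < N)
      pts[b].push_back(std::make_pair(double(N), z_max));
    // linear interpolation over stages 0..N
    size_t k = 0;
    for (int s = 0; s <= N; ++s) {
      while (k + 1 < pts[b].size() && pts[b][k + 1].first < s) ++k;
      double x0 = pts[b][k].first, y0 = pts[b][k].second;
      double g;
      if (k + 1 >= pts[b].size()) {
        g = y0; // constant beyond last control point
      } else {
        double x1 = pts[b][k + 1].first, y1 = pts[b][k + 1].second;
        g = (s <= x0) ? y0 : y0 + (y1 - y0) * (double(s) - x0) / (x1 - x0);
      }
      G[(size_t)b * (N + 1) + s] = g;
    }
  }
}

// log-likelihood matrix: LL[i][s] = sum_b log N(z_ib; G_b(s), sigma), NaN skipped
static void loglik_matrix(const NumericMatrix &Z,
                          const std::vector<double> &G,
                          double sigma, int N,
                          std::vector<double> &LL /* n x (N+1), row-major */) {
  const int n = Z.nrow(), B = Z.ncol();
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double lognorm = -0.5 * LOG_2PI - std::log(sigma);
  std::fill(LL.begin(), LL.end(), 0.0);
  for (int b = 0; b < B; ++b) {
    const double *g = &G[(size_t)b * (N + 1)];
    for (int i = 0; i < n; ++i) {
      double z = Z(i, b);
      if (ISNAN(z)) continue;
      double *row = &LL[(size_t)i * (N + 1)];
      for (int s = 0; s <= N; ++s) {
        double d = z - g[s];
        row[s] += lognorm - d * d * inv2s2;
      }
    }
  }
}

// per-subject marginal log-likelihood under a stage prior (log scale)
static double total_loglik(const std::vector<double> &LL, int n, int N,
                           const NumericVector &logprior,
                           const NumericVector &weights) {
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    const double *row = &LL[(size_t)i * (N + 1)];
    double m = R_NegInf;
    for (int s = 0; s <= N; ++s) {
      double v = row[s] + logprior[s];
      if (v > m) m = v;
    }
    double acc = 0.0;
    for (int s = 0; s <= N; ++s) {
      double v = row[s] + logprior[s] - m;
      if (v > -37.0) acc += std::exp(v);  // below this exp() underflows the sum
    }
    total += weights[i] * (m + std::log(acc));
  }
  return total;
}

static double seq_loglik(const NumericMatrix &Z, const std::vector<int> &seq,
                         const IntegerVector &bio, const NumericVector &zval,
                         int n_bio, double sigma, double z_max,
                         const NumericVector &logprior,
                         const NumericVector &weights) {
  const int N = seq.size(), n = Z.nrow();
  std::vector<double> G((size_t)n_bio * (N + 1));
  std::vector<double> LL((size_t)n * (N + 1));
  build_trajectory(seq, bio, zval, n_bio, z_max, G);
  loglik_matrix(Z, G, sigma, N, LL);
  return total_loglik(LL, n, N, logprior, weights);
}

// move event at position `from` to position `to` (both 0-based), then restore
// ascending threshold order within the moved event's biomarker
static void move_event(std::vector<int> &seq, int from, int to,
                       const IntegerVector &bio, const NumericVector &zval) {
  int e = seq[from];
  seq.erase(seq.begin() + from);
  seq.insert(seq.begin() + to, e);
  // canonicalize the biomarker of e: events ascending in threshold
  int b = bio[e];
  std::vector<int> pos, ids;
  for (size_t p = 0; p < seq.size(); ++p)
    if (bio[seq[p]] == b) { pos.push_back(p); ids.push_back(seq[p]); }
  std::sort(ids.begin(), ids.end(),
            [&](int a, int c) { return zval[a] < zval[c]; });
  for (size_t k = 0; k < pos.size(); ++k) seq[pos[k]] = ids[k];
}

// [[Rcpp::export]]
NumericMatrix ebm_loglik_matrix_cpp(NumericMatrix Z, IntegerVector seq0,
                                    IntegerVector bio, NumericVector zval,
                                    int n_bio, double sigma, double z_max) {
  const int N = seq0.size(), n = Z.nrow();
  std::vector<int> seq(seq0.begin(), seq0.end());
  std::vector<double> G((size_t)n_bio * (N + 1));
  std::vector<double> LL((size_t)n * (N + 1));
  build_trajectory(seq, bio, zval, n_bio, z_max, G);
  loglik_matrix(Z, G, sigma, N, LL);
  NumericMatrix out(n, N + 1);
  for (int i = 0; i < n; ++i)
    for (int s = 0; s <= N; ++s) out(i, s) = LL[(size_t)i * (N + 1) + s];
  return out;
}

// [[Rcpp::export]]
NumericMatrix ebm_trajectory_cpp(IntegerVector seq0, IntegerVector bio,
                                 NumericVector zval, int n_bio, double z_max) {
  const int N = seq0.size();
  std::vector<int> seq(seq0.begin(), seq0.end());
  std::vector<double> G((size_t)n_bio * (N + 1));
  build_trajectory(seq, bio, zval, n_bio, z_max, G);
  NumericMatrix out(N + 1, n_bio);
  for (int b = 0; b < n_bio; ++b)
    for (int s = 0; s <= N; ++s) out(s, b) = G[(size_t)b * (N + 1) + s];
  return out;
}

// [[Rcpp::export]]
double ebm_total_loglik_cpp(NumericMatrix Z, IntegerVector seq0,
                            IntegerVector bio, NumericVector zval, int n_bio,
                            double sigma, double z_max, NumericVector logprior,
                            NumericVector weights) {
  std::vector<int> seq(seq0.begin(), seq0.end());
  return seq_loglik(Z, seq, bio, zval, n_bio, sigma, z_max, logprior, weights);
}

// greedy ascent by single-event repositioning: cycle over events in random
// order, moving each to its best valid position (within the window allowed by
// its within-biomarker neighbours), until a full pass yields no gain
// [[Rcpp::export]]
List ebm_greedy_cpp(NumericMatrix Z, IntegerVector seq0, IntegerVector bio,
                    NumericVector zval, int n_bio, double sigma, double z_max,
                    NumericVector logprior, NumericVector weights,
                    int max_sweeps = 200) {
  const int N = seq0.size();
  std::vector<int> seq(seq0.begin(), seq0.end());
  double cur = seq_loglik(Z, seq, bio, zval, n_bio, sigma, z_max, logprior, weights);

  std::vector<std::vector<int> > bevents(n_bio);
  for (int e = 0; e < N; ++e) bevents[bio[e]].push_back(e);
  for (int b = 0; b < n_bio; ++b)
    std::sort(bevents[b].begin(), bevents[b].end(),
              [&](int a, int c) { return zval[a] < zval[c]; });

  std::vector<int> order(N), pos_of(N);
  for (int e = 0; e < N; ++e) order[e] = e;
  int sweeps = 0;
  for (; sweeps < max_sweeps; ++sweeps) {
    bool improved = false;
    // random visiting order (uses R's RNG)
    for (int i = N - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    for (int oi = 0; oi < N; ++oi) {
      int e = order[oi];
      for (int p = 0; p < N; ++p) pos_of[seq[p]] = p;
      int b = bio[e];
      int k = 0;
      while (bevents[b][k] != e) ++k;
      int low = (k > 0) ? pos_of[bevents[b][k - 1]] + 1 : 0;
      int high = (k + 1 < (int)bevents[b].size()) ? pos_of[bevents[b][k + 1]] - 1
                                                  : N - 1;
      int from = pos_of[e];
      double best_ll = cur;
      int best_to = -1;
      for (int to = low; to <= high; ++to) {
        if (to == from) continue;
        std::vector<int> cand(seq);
        cand.erase(cand.begin() + from);
        cand.insert(cand.begin() + to, e);
        double ll = seq_loglik(Z, cand, bio, zval, n_bio, sigma, z_max,
                               logprior, weights);
        if (ll > best_ll + 1e-12) { best_ll = ll; best_to = to; }
      }
      if (best_to >= 0) {
        seq.erase(seq.begin() + from);
        seq.insert(seq.begin() + best_to, e);
        cur = best_ll;
        improved = true;
      }
    }
    if (!improved) break;
  }
  return List::create(_["sequence"] = IntegerVector(seq.begin(), seq.end()),
                      _["loglik"] = cur, _["sweeps"] = sweeps);
}

// Metropolis chain over valid sequences: propose moving a random event to a
// random position inside the window allowed by its within-biomarker neighbours,
// accept with min(1, likelihood ratio). Uses R's RNG (seed via set.seed()).
// [[Rcpp::export]]
List ebm_mcmc_cpp(NumericMatrix Z, IntegerVector seq0, IntegerVector bio,
                  NumericVector zval, int n_bio, double sigma, double z_max,
                  NumericVector logprior, NumericVector weights, int n_iter) {
  const int N = seq0.size();
  std::vector<int> seq(seq0.begin(), seq0.end());
  double cur = seq_loglik(Z, seq, bio, zval, n_bio, sigma, z_max, logprior, weights);
  std::vector<int> best(seq);
  double best_ll = cur;

  // per-biomarker event ids in ascending threshold order
  std::vector<std::vector<int> > bevents(n_bio);
  for (int e = 0; e < N; ++e) bevents[bio[e]].push_back(e);
  for (int b = 0; b < n_bio; ++b)
    std::sort(bevents[b].begin(), bevents[b].end(),
              [&](int a, int c) { return zval[a] < zval[c]; });

  IntegerMatrix samples(n_iter, N);
  NumericVector lls(n_iter);
  int accepted = 0;
  std::vector<int> pos_of(N);

  for (int it = 0; it < n_iter; ++it) {
    for (int p = 0; p < N; ++p) pos_of[seq[p]] = p;
    int e = (int)std::floor(unif_rand() * N);
    if (e >= N) e = N - 1;
    int b = bio[e];
    // rank of e among its biomarker's events
    int k = 0;
    while (bevents[b][k] != e) ++k;
    int low = (k > 0) ? pos_of[bevents[b][k - 1]] + 1 : 0;
    int high = (k + 1 < (int)bevents[b].size()) ? pos_of[bevents[b][k + 1]] - 1
                                                : N - 1;
    int span = high - low + 1;
    int to = low + (int)std::floor(unif_rand() * span);
    if (to > high) to = high;
    int from = pos_of[e];
    if (to != from) {
      std::vector<int> cand(seq);
      move_event(cand, from, to, bio, zval);
      double ll = seq_loglik(Z, cand, bio, zval, n_bio, sigma, z_max,
                             logprior, weights);
      if (std::log(unif_rand()) < ll - cur) {
        seq = cand;
        cur = ll;
        ++accepted;
        if (cur > best_ll) { best_ll = cur; best = seq; }
      }
    }
    for (int p = 0; p < N; ++p) samples(it, p) = seq[p];
    lls[it] = cur;
  }
  return List::create(_["samples"] = samples, _["loglik"] = lls,
                      _["ml_sequence"] = IntegerVector(best.begin(), best.end()),
                      _["ml_loglik"] = best_ll,
                      _["acceptance_rate"] = n_iter > 0 ? double(accepted) / n_iter : NA_REAL);
}
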