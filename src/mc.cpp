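#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// median of values in buf[0..n); buf is scratch and gets reordered
static double med_inplace(std::vector<double>& buf) {
  const size_t n = buf.size();
  if (n == 0) return NA_REAL;
  const size_t h = n / 2;
  std::nth_element(buf.begin(), buf.begin() + h, buf.end());
  double hi = buf[h];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(buf.begin(), buf.begin() + h);
  return (lo + hi) / 2.0;
}

// partial Fisher-Yates: reorders idx so its first N entries are a uniform
// sample without replacement; uses R's RNG so set.seed() reproduces
static void draw_sample(std::vector<int>& idx, int N) {
  const int U = (int)idx.size();
  for (int i = 0; i < N; ++i) {
    int j = i + (int)(unif_rand() * (U - i));
    if (j >= U) j = U - 1;
    std::swap(idx[i], idx[j]);
  }
}

// Resampling null for ordered-context median supersaturation.
//
// sigma: universe x n_contexts matrix of recentered scores, NA where a
// protein is absent from a context. Per trial, N row indices are drawn
// uniformly without replacement (R's RNG, so set.seed() reproduces);
// the median over sampled, present proteins is taken per context.
//
// Returns, per trial criterion:
//   exceed_strict  = #trials with min(med) > 0 and strictly increasing
//   exceed_relaxed = #trials strictly increasing
// plus per-context counts of trials with zero sampled present proteins
// (such a context yields an undefined median and the trial scores 0).
// [[Rcpp::export(name = ".mc_escalation")]]
List mc_escalation(NumericMatrix sigma, int N, int K) {
  const int U = sigma.nrow(), C = sigma.ncol();
  if (N > U) stop("N exceeds universe size");
  long strict = 0, relaxed = 0;
  IntegerVector zero_ctx(C);
  std::vector<double> buf;
  buf.reserve(N);
  std::vector<double> med(C);
  std::vector<int> idx(U);
  for (int i = 0; i < U; ++i) idx[i] = i;
  for (int k = 0; k < K; ++k) {
    draw_sample(idx, N);
    bool ok = true;
    for (int c = 0; c < C; ++c) {
      buf.clear();
      for (int i = 0; i < N; ++i) {
        double v = sigma(idx[i], c);
        if (!NumericVector::is_na(v)) buf.push_back(v);
      }
      if (buf.empty()) { zero_ctx[c]++; ok = false; med[c] = NA_REAL; }
      else med[c] = med_inplace(buf);
    }
    if (!ok) continue;  // undefined median: E_k = 0 under both criteria
    bool inc = true;
    for (int c = 1; c < C; ++c)
      if (!(med[c] > med[c - 1])) { inc = false; break; }
    if (!inc) continue;
    relaxed++;
    double mn = med[0];
    for (int c = 1; c < C; ++c) if (med[c] < mn) mn = med[c];
    if (mn > 0) strict++;
  }
  return List::create(_["exceed_strict"] = (double)strict,
                      _["exceed_relaxed"] = (double)relaxed,
                      _["zero_context_trials"] = zero_ctx);
}

// Resampling null for the difference in median supersaturation between two
// contexts. sigma: universe x 2; per trial dd_k = med2 - med1 over sampled
// present proteins; exceed counts trials with dd_k > observed.
// [[Rcpp::export(name = ".mc_comparative")]]
List mc_comparative(NumericMatrix sigma, int N, int K, double observed) {
  if (sigma.ncol() != 2) stop("expected two contexts");
  const int U = sigma.nrow();
  if (N > U) stop("N exceeds universe size");
  long exceed = 0;
  IntegerVector zero_ctx(2);
  std::vector<double> b1, b2;
  b1.reserve(N); b2.reserve(N);
  std::vector<int> idx(U);
  for (int i = 0; i < U; ++i) idx[i] = i;
  for (int k = 0; k < K; ++k) {
    draw_sample(idx, N);
    b1.clear(); b2.clear();
    for (int i = 0; i < N; ++i) {
      double v1 = sigma(idx[i], 0), v2 = sigma(idx[i], 1);
      if (!NumericVector::is_na(v1)) b1.push_back(v1);
      if (!NumericVector::is_na(v2)) b2.push_back(v2);
    }
    if (b1.empty()) zero_ctx[0]++;
    if (b2.empty()) zero_ctx[1]++;
    if (b1.empty() || b2.empty()) continue;  // E_k = 0
    double dd = med_inplace(b2) - med_inplace(b1);
    if (dd > observed) exceed++;
  }
  return List::create(_["exceed"] = (double)exceed,
                      _["zero_context_trials"] = zero_ctx);
}
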