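#include <Rcpp.h>
#include <random>
#include <numeric>
using namespace Rcpp;

// Stochastic-gradient-descent matrix factorization over observed entries
// only (Funk's recommender-system scheme).  Factors are updated jointly
// across all ranks for each visited entry; the visiting order is reshuffled
// every epoch with a private mt19937 stream so fits are bit-reproducible
// for a given seed, independent of R's RNG state.
// [[Rcpp::export]]
List funk_svd_sgd(NumericMatrix x, LogicalMatrix obs, int rank,
                  double learning_rate, double regularization,
                  int max_epochs, double tol, int seed,
                  double init_range) {
  const int nr = x.nrow(), nc = x.ncol();
  std::vector<int> oi, oj;
  oi.reserve((size_t)nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (obs(i, j)) { oi.push_back(i); oj.push_back(j); }
  const int m = (int)oi.size();
  if (m == 0) stop("no observed entries");

  std::mt19937 rng((uint32_t)seed);
  std::uniform_real_distribution<double> unif(-init_range, init_range);
  NumericMatrix U(nr, rank), V(nc, rank);
  for (int k = 0; k < rank; ++k) {
    for (int i = 0; i < nr; ++i) U(i, k) = unif(rng);
    for (int j = 0; j < nc; ++j) V(j, k) = unif(rng);
  }

  std::vector<int> idx(m);
  std::iota(idx.begin(), idx.end(), 0);
  std::vector<double> trace;
  trace.reserve(max_epochs);
  double prev = R_PosInf;
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(idx.begin(), idx.end(), rng);
    for (int t = 0; t < m; ++t) {
      const int i = oi[idx[t]], j = oj[idx[t]];
      double pred = 0.0;
      for (int k = 0; k < rank; ++k) pred += U(i, k) * V(j, k);
      const double err = x(i, j) - pred;
      for (int k = 0; k < rank; ++k) {
        const double u = U(i, k), v = V(j, k);
        U(i, k) += learning_rate * (err * v - regularization * u);
        V(j, k) += learning_rate * (err * u - regularization * v);
      }
    }
    double sse = 0.0;
    for (int t = 0; t < m; ++t) {
      const int i = oi[t], j = oj[t];
      double pred = 0.0;
      for (int k = 0; k < rank; ++k) pred += U(i, k) * V(j, k);
      const double e = x(i, j) - pred;
      sse += e * e;
    }
    const double rmse = std::sqrt(sse / m);
    if (!std::isfinite(rmse)) {
      stop("training diverged (RMSE is not finite); reduce learning_rate");
    }
    trace.push_back(rmse);
    if (epoch > 0 && prev - rmse < tol) break;
    prev = rmse;
  }
  return List::create(_["U"] = U, _["V"] = V,
                      _["rmse_trace"] = wrap(trace));
}
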