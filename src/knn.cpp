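#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Squared Euclidean distance between two columns of length d, summed in
// storage order so results are reproducible across call sites.
static inline double col_sqdist(const double* a, const double* b, const int d) {
  double s = 0.0;
  for (int j = 0; j < d; ++j) {
    const double diff = a[j] - b[j];
    s += diff * diff;
  }
  return s;
}

// Running top-k selection over (distance, index) pairs scanned in ascending
// index order. Strict comparison keeps the earlier (lower) index on ties,
// implementing the documented tie-break without a sort.
struct TopK {
  int k, count;
  std::vector<double> dist;
  std::vector<int> idx;
  explicit TopK(int k_) : k(k_), count(0), dist(k_), idx(k_) {}
  void reset() { count = 0; }
  inline void offer(double d, int i) {
    if (count == k && d >= dist[count - 1]) return;
    int pos = (count < k) ? count : k - 1;
    while (pos > 0 && d < dist[pos - 1]) {
      dist[pos] = dist[pos - 1];
      idx[pos] = idx[pos - 1];
      --pos;
    }
    dist[pos] = d;
    idx[pos] = i;
    if (count < k) ++count;
  }
  inline double mean_of(const double* y) const {
    double s = 0.0;
    for (int i = 0; i < count; ++i) s += y[idx[i]];
    return s / count;
  }
};

// kNN regression of each query column against a pool of reference columns.
// exclude holds, per query, the 1-based pool column to skip (0 = none).
// [[Rcpp::export]]
NumericVector cpp_knn_predict(NumericMatrix pool, NumericVector y,
                              NumericMatrix queries, int k,
                              IntegerVector exclude) {
  const int d = pool.nrow(), n = pool.ncol(), m = queries.ncol();
  if (queries.nrow() != d) stop("query dimension does not match pool");
  if (y.size() != n) stop("pool values do not match pool columns");
  if (exclude.size() != m) stop("one exclusion entry required per query");
  if (k < 1) stop("k must be at least 1");
  NumericVector out(m);
  const double* P = REAL(pool);
  const double* Y = REAL(y);
  TopK top(k);
  for (int q = 0; q < m; ++q) {
    const int ex = exclude[q] - 1;
    const int eligible = (ex >= 0 && ex < n) ? n - 1 : n;
    if (eligible < k)
      stop("insufficient neighbours: k = %d but only %d eligible pool samples",
           k, eligible);
    const double* qc = &queries(0, q);
    top.reset();
    for (int i = 0; i < n; ++i) {
      if (i == ex) continue;
      top.offer(col_sqdist(P + (size_t)i * d, qc, d), i);
    }
    out[q] = top.mean_of(Y);
  }
  return out;
}

// Leave-one-out kNN predictions over all columns of X.
// [[Rcpp::export]]
NumericVector cpp_loo_predict(NumericMatrix X, NumericVector y, int k) {
  const int d = X.nrow(), n = X.ncol();
  if (y.size() != n) stop("response length does not match sample count");
  if (k < 1) stop("k must be at least 1");
  if (n - 1 < k)
    stop("insufficient neighbours: k = %d but only %d eligible pool samples",
         k, n - 1);
  const double* P = REAL(X);
  std::vector<double> D((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    const double* ci = P + (size_t)i * d;
    for (int j = i + 1; j < n; ++j) {
      const double s = col_sqdist(ci, P + (size_t)j * d, d);
      D[(size_t)i * n + j] = s;
      D[(size_t)j * n + i] = s;
    }
  }
  NumericVector out(n);
  const double* Y = REAL(y);
  TopK top(k);
  for (int i = 0; i < n; ++i) {
    const double* row = D.data() + (size_t)i * n;
    top.reset();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      top.offer(row[j], j);
    }
    out[i] = top.mean_of(Y);
  }
  return out;
}

// Leave-one-out squared-error loss: the GA fitness hot path.
// [[Rcpp::export]]
double cpp_loo_sse(NumericMatrix X, NumericVector y, int k) {
  NumericVector p = cpp_loo_predict(X, y, k);
  double s = 0.0;
  for (int i = 0; i < X.ncol(); ++i) {
    const double d = y[i] - p[i];
    s += d * d;
  }
  return s;
}
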