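#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Maintain the k nearest neighbours under the total order
// (squared distance, training index): ties in distance resolve to the
// smaller index, which makes predictions deterministic and invariant to
// training-sample permutation once a canonical index order is fixed.
struct TopK {
  int k, size;
  std::vector<double> d;
  std::vector<int> idx;
  explicit TopK(int k_) : k(k_), size(0), d(k_), idx(k_) {}
  void reset() { size = 0; }
  inline bool before(double dj, int j, double di, int i) const {
    return dj < di || (dj == di && j < i);
  }
  inline void offer(double dj, int j) {
    if (size == k && !before(dj, j, d[k - 1], idx[k - 1])) return;
    int pos = size < k ? size : k - 1;
    while (pos > 0 && before(dj, j, d[pos - 1], idx[pos - 1])) {
      d[pos] = d[pos - 1];
      idx[pos] = idx[pos - 1];
      --pos;
    }
    d[pos] = dj;
    idx[pos] = j;
    if (size < k) ++size;
  }
};

// Strict-majority vote among the k nearest neighbours: the 1-based class
// code held by more than k/2 of them, or 0 (reject) when none reaches a
// strict majority.
static int vote(const TopK &nn, const IntegerVector &labels, int n_classes,
                std::vector<int> &cnt) {
  std::fill(cnt.begin(), cnt.end(), 0);
  for (int j = 0; j < nn.k; ++j) {
    int c = labels[nn.idx[j]];
    if (2 * (++cnt[c]) > nn.k) return c;
  }
  return 0;
}

// [[Rcpp::export]]
IntegerVector knn_predict_cpp(NumericMatrix train, IntegerVector labels,
                              NumericMatrix query, int k, int n_classes) {
  const int p = train.nrow(), n = train.ncol(), m = query.ncol();
  IntegerVector pred(m);
  TopK nn(k);
  std::vector<int> cnt(n_classes + 1);
  const double *tr = REAL(train);
  const double *qu = REAL(query);
  for (int q = 0; q < m; ++q) {
    nn.reset();
    const double *qc = qu + (size_t)q * p;
    for (int j = 0; j < n; ++j) {
      const double *tc = tr + (size_t)j * p;
      double s = 0.0;
      for (int g = 0; g < p; ++g) {
        double d = tc[g] - qc[g];
        s += d * d;
      }
      nn.offer(s, j);
    }
    pred[q] = vote(nn, labels, n_classes, cnt);
  }
  return pred;
}

// Leave-one-out training fitness: fraction of training samples whose
// prediction (self excluded from its own neighbour search) matches the
// label; rejected samples count as incorrect.
// [[Rcpp::export]]
double knn_loo_fitness_cpp(NumericMatrix train, IntegerVector labels, int k,
                           int n_classes) {
  const int p = train.nrow(), n = train.ncol();
  const double *tr = REAL(train);
  std::vector<double> d2((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    const double *ci = tr + (size_t)i * p;
    for (int j = i + 1; j < n; ++j) {
      const double *cj = tr + (size_t)j * p;
      double s = 0.0;
      for (int g = 0; g < p; ++g) {
        double d = ci[g] - cj[g];
        s += d * d;
      }
      d2[(size_t)i * n + j] = s;
      d2[(size_t)j * n + i] = s;
    }
  }
  TopK nn(k);
  std::vector<int> cnt(n_classes + 1);
  int correct = 0;
  for (int i = 0; i < n; ++i) {
    nn.reset();
    const double *row = d2.data() + (size_t)i * n;
    for (int j = 0; j < n; ++j) {
      if (j != i) nn.offer(row[j], j);
    }
    if (vote(nn, labels, n_classes, cnt) == labels[i]) ++correct;
  }
  return (double)correct / n;
}
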