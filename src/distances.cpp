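// Distributional distance kernels for variable-length embedding matrices.
// Energy distance uses the sorted-sample O(n log n) identities; the 1-D earth
// mover's distance integrates |F_x - F_y| over the merged support.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// sum_{i<j} (x_(j) - x_(i)) for a sorted vector, i.e. half the sum of all
// ordered-pair absolute differences (self pairs contribute zero).
static double sorted_self_sum(const arma::vec &xs) {
  const arma::uword n = xs.n_elem;
  double acc = 0.0;
  for (arma::uword j = 0; j < n; ++j)
    acc += (2.0 * static_cast<double>(j) + 1.0 - static_cast<double>(n)) * xs[j];
  return acc;
}

// sum_i sum_j |x_i - y_j| for two sorted vectors (merge walk).
static double sorted_cross_sum(const arma::vec &xs, const arma::vec &ys) {
  const arma::uword n = xs.n_elem, m = ys.n_elem;
  // prefix sums of xs
  double sx_tot = arma::accu(xs);
  double acc = 0.0;
  arma::uword k = 0;      // number of xs <= current y
  double sx_k = 0.0;      // sum of those xs
  for (arma::uword j = 0; j < m; ++j) {
    const double yj = ys[j];
    while (k < n && xs[k] <= yj) { sx_k += xs[k]; ++k; }
    const double kk = static_cast<double>(k);
    acc += yj * kk - sx_k + (sx_tot - sx_k) - yj * (static_cast<double>(n) - kk);
  }
  return acc;
}

static double energy_sorted(const arma::vec &xs, const arma::vec &ys,
                            double self_x, double self_y) {
  const double n = xs.n_elem, m = ys.n_elem;
  const double cross = sorted_cross_sum(xs, ys) / (n * m);
  return 2.0 * cross - 2.0 * self_x / (n * n) - 2.0 * self_y / (m * m);
}

static double emd_sorted(const arma::vec &xs, const arma::vec &ys) {
  const arma::uword n = xs.n_elem, m = ys.n_elem;
  double acc = 0.0;
  arma::uword i = 0, j = 0;
  double prev = std::min(xs[0], ys[0]);
  while (i < n || j < m) {
    double cur;
    if (i < n && (j >= m || xs[i] <= ys[j])) cur = xs[i];
    else cur = ys[j];
    const double fx = static_cast<double>(i) / n;
    const double fy = static_cast<double>(j) / m;
    acc += std::abs(fx - fy) * (cur - prev);
    prev = cur;
    if (i < n && (j >= m || xs[i] <= ys[j])) ++i; else ++j;
  }
  return acc;
}

// [[Rcpp::export]]
double cpp_energy_distance(const arma::vec &x, const arma::vec &y) {
  arma::vec xs = arma::sort(x), ys = arma::sort(y);
  return energy_sorted(xs, ys, sorted_self_sum(xs), sorted_self_sum(ys));
}

// [[Rcpp::export]]
double cpp_emd1d(const arma::vec &x, const arma::vec &y) {
  arma::vec xs = arma::sort(x), ys = arma::sort(y);
  return emd_sorted(xs, ys);
}

// Mean over embedding dimensions of the per-dimension distance between the
// time marginals of two embedding matrices (rows = dimensions, cols = epochs).
// [[Rcpp::export]]
double cpp_embedding_pair_distance(const arma::mat &a, const arma::mat &b,
                                   const std::string &metric) {
  const arma::uword d = a.n_rows;
  double acc = 0.0;
  for (arma::uword r = 0; r < d; ++r) {
    arma::vec xs = arma::sort(a.row(r).t());
    arma::vec ys = arma::sort(b.row(r).t());
    if (metric == "energy")
      acc += energy_sorted(xs, ys, sorted_self_sum(xs), sorted_self_sum(ys));
    else
      acc += emd_sorted(xs, ys);
  }
  return acc / static_cast<double>(d);
}

// Full pairwise distance matrix. Rows of each embedding are sorted once.
// [[Rcpp::export]]
arma::mat cpp_pairwise_embedding_distance(const List &embeddings,
                                          const std::string &metric) {
  const int n = embeddings.size();
  std::vector<arma::mat> sorted(n);
  std::vector<arma::vec> selfsum(n);
  int d = -1;
  for (int i = 0; i < n; ++i) {
    arma::mat e = as<arma::mat>(embeddings[i]);
    if (d < 0) d = e.n_rows;
    arma::mat s(e.n_rows, e.n_cols);
    arma::vec ss(e.n_rows, arma::fill::zeros);
    for (arma::uword r = 0; r < e.n_rows; ++r) {
      arma::rowvec row = arma::sort(e.row(r));
      s.row(r) = row;
      if (metric == "energy") ss[r] = sorted_self_sum(row.t());
    }
    sorted[i] = s;
    selfsum[i] = ss;
  }
  arma::mat D(n, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double acc = 0.0;
      for (int r = 0; r < d; ++r) {
        arma::vec xs = sorted[i].row(r).t();
        arma::vec ys = sorted[j].row(r).t();
        if (metric == "energy")
          acc += energy_sorted(xs, ys, selfsum[i][r], selfsum[j][r]);
        else
          acc += emd_sorted(xs, ys);
      }
      D(i, j) = D(j, i) = acc / d;
    }
  }
  return D;
}
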