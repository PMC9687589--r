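#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Kraskov-Stoegbauer-Grassberger mutual information (estimator 1).
// O(n^2); max-norm in the joint space, strict-inequality marginal counts.
// [[Rcpp::export]]
double mi_ksg_cpp(NumericVector x, NumericVector y, int k = 3) {
  const int n = x.size();
  if (n != y.size()) stop("length mismatch");
  if (k >= n) stop("k must be < n");
  std::vector<double> dx(n), dy(n), dj(n - 1);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      dx[m] = std::fabs(x[i] - x[j]);
      dy[m] = std::fabs(y[i] - y[j]);
      dj[m] = std::max(dx[m], dy[m]);
      ++m;
    }
    std::vector<double> djs(dj);
    std::nth_element(djs.begin(), djs.begin() + (k - 1), djs.end());
    const double eps = djs[k - 1];
    int nx = 0, ny = 0;
    for (int j = 0; j < m; ++j) {
      if (dx[j] < eps) ++nx;
      if (dy[j] < eps) ++ny;
    }
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
  }
  return R::digamma((double)k) + R::digamma((double)n) - acc / n;
}

// KSG mutual information for every channel pair of one epoch (K x n matrix).
// Per-channel distance matrices are computed once and shared across pairs.
// Returns a K x K symmetric matrix (diagonal 0); constant channels give 0.
// [[Rcpp::export]]
NumericMatrix mi_ksg_matrix_cpp(NumericMatrix x, int k = 3) {
  const int K = x.nrow(), n = x.ncol();
  if (k >= n) stop("k must be < n");
  // distance matrices, row-major n*n per channel
  std::vector<std::vector<double> > D(K);
  std::vector<bool> constant(K, false);
  for (int c = 0; c < K; ++c) {
    double mn = x(c, 0), mx = x(c, 0);
    for (int t = 1; t < n; ++t) {
      mn = std::min(mn, x(c, t));
      mx = std::max(mx, x(c, t));
    }
    constant[c] = (mx - mn) == 0.0;
    if (constant[c]) continue;
    D[c].resize((size_t)n * n);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        D[c][(size_t)i * n + j] = std::fabs(x(c, i) - x(c, j));
  }
  NumericMatrix out(K, K);
  std::vector<double> psi(n + 1);            // digamma lookup, psi[m] = digamma(m)
  for (int m = 1; m <= n; ++m) psi[m] = R::digamma((double)m);
  const double psi_k = psi[k], psi_n = psi[n];
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> best(k);
  for (int a = 0; a < K - 1; ++a) {
    if (constant[a]) continue;
    for (int b = a + 1; b < K; ++b) {
      if (constant[b]) continue;
      double acc = 0.0;
      for (int i = 0; i < n; ++i) {
        const double *da = &D[a][(size_t)i * n];
        const double *db = &D[b][(size_t)i * n];
        // k smallest joint distances by insertion (k is tiny)
        for (int m = 0; m < k; ++m) best[m] = inf;
        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          double v = std::max(da[j], db[j]);
          if (v < best[k - 1]) {
            int m = k - 1;
            while (m > 0 && v < best[m - 1]) { best[m] = best[m - 1]; --m; }
            best[m] = v;
          }
        }
        const double eps = best[k - 1];
        int nx = 0, ny = 0;
        for (int j = 0; j < n; ++j) {
          nx += da[j] < eps;
          ny += db[j] < eps;
        }
        if (eps > 0) { --nx; --ny; }         // self-distance 0 was counted
        acc += psi[nx + 1] + psi[ny + 1];
      }
      double mi = psi_k + psi_n - acc / n;
      out(a, b) = out(b, a) = mi;
    }
  }
  return out;
}

// Simulate X(t) = sum_m A_m X(t-m) + E(t) for a K-channel order-p process.
// A is K x (K*p): columns [A_1 | A_2 | ... | A_p]; innov is K x (n + burn).
// Returns the last n columns.
// [[Rcpp::export]]
NumericMatrix simulate_mvar_cpp(NumericMatrix A, int p, NumericMatrix innov,
                                int burn) {
  const int K = A.nrow();
  const int total = innov.ncol();
  if (A.ncol() != K * p) stop("A must be K x (K*p)");
  if (total <= burn + p) stop("too few innovation samples");
  NumericMatrix X(K, total);
  for (int t = 0; t < total; ++t) {
    for (int i = 0; i < K; ++i) X(i, t) = innov(i, t);
    if (t >= p) {
      for (int m = 1; m <= p; ++m) {
        const int off = (m - 1) * K;
        for (int i = 0; i < K; ++i) {
          double s = 0.0;
          for (int j = 0; j < K; ++j) s += A(i, off + j) * X(j, t - m);
          X(i, t) += s;
        }
      }
    }
  }
  NumericMatrix out(K, total - burn);
  for (int t = burn; t < total; ++t)
    for (int i = 0; i < K; ++i) out(i, t - burn) = X(i, t);
  return out;
}
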