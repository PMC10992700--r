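#include <Rcpp.h>
using namespace Rcpp;

// Discrete Frechet distance between point sequences (ax, ay) and (bx, by)
// with the Euclidean point metric: the minimum over monotone couplings of
// the maximum pointwise distance, by the standard dynamic programme.
static double dfrechet(const double* ax, const double* ay, int n,
                       const double* bx, const double* by, int m) {
  std::vector<double> ca(n * m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double dx = ax[i] - bx[j], dy = ay[i] - by[j];
      double d = std::sqrt(dx * dx + dy * dy);
      double prev;
      if (i == 0 && j == 0) {
        prev = 0.0;
      } else if (i == 0) {
        prev = ca[j - 1];
      } else if (j == 0) {
        prev = ca[(i - 1) * m];
      } else {
        prev = std::min(ca[(i - 1) * m + j],
                        std::min(ca[(i - 1) * m + j - 1], ca[i * m + j - 1]));
      }
      ca[i * m + j] = std::max(prev, d);
    }
  }
  return ca[n * m - 1];
}

// [[Rcpp::export]]
double cpp_discrete_frechet(NumericVector ax, NumericVector ay,
                            NumericVector bx, NumericVector by) {
  return dfrechet(ax.begin(), ay.begin(), ax.size(),
                  bx.begin(), by.begin(), bx.size());
}

// Pairwise discrete Frechet distances between the rows of `values`, all
// sharing the time grid `times`.
// [[Rcpp::export]]
NumericMatrix cpp_frechet_matrix(NumericMatrix values, NumericVector times) {
  int n = values.nrow(), p = values.ncol();
  std::vector<double> tx(times.begin(), times.end());
  NumericMatrix d(n, n);
  std::vector<double> vi(p), vj(p);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < p; ++c) vi[c] = values(i, c);
    for (int j = i + 1; j < n; ++j) {
      for (int c = 0; c < p; ++c) vj[c] = values(j, c);
      double dij = dfrechet(tx.data(), vi.data(), p, tx.data(), vj.data(), p);
      d(i, j) = dij;
      d(j, i) = dij;
    }
  }
  return d;
}
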