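#include <Rcpp.h>
using namespace Rcpp;

// Banded DTW accumulated-cost matrix for the symmetric step pattern with
// slope constraint P = 0: diagonal steps weigh the local cost twice,
// horizontal/vertical steps once, and the (1,1) cell is costed as a
// diagonal entry (g11 = 2*|x1 - y1|).  Cells with |i - j| > w are
// infeasible.  `window` may be R_PosInf for an unconstrained alignment.
static void fill_cost(const NumericVector& x, const NumericVector& y,
                      double window, NumericMatrix& g) {
  const int n = x.size(), m = y.size();
  const double inf = R_PosInf;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      g(i, j) = inf;
  g(0, 0) = 2.0 * std::abs(x[0] - y[0]);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      if (i == 0 && j == 0) continue;
      if (std::abs(i - j) > window) continue;
      double c = std::abs(x[i] - y[j]);
      double best = inf;
      if (i > 0 && j > 0 && g(i - 1, j - 1) < inf)
        best = g(i - 1, j - 1) + 2.0 * c;
      if (i > 0 && g(i - 1, j) < inf)
        best = std::min(best, g(i - 1, j) + c);
      if (j > 0 && g(i, j - 1) < inf)
        best = std::min(best, g(i, j - 1) + c);
      g(i, j) = best;
    }
  }
}

// [[Rcpp::export(name = ".cpp_dtw_cost")]]
double cpp_dtw_cost(NumericVector x, NumericVector y, double window) {
  NumericMatrix g(x.size(), y.size());
  fill_cost(x, y, window, g);
  return g(x.size() - 1, y.size() - 1);
}

// Full alignment: accumulated cost plus one optimal warping path, recovered
// by backtracking with the deterministic preference diagonal > vertical
// (step in i) > horizontal (step in j).
// [[Rcpp::export(name = ".cpp_dtw_align")]]
List cpp_dtw_align(NumericVector x, NumericVector y, double window) {
  const int n = x.size(), m = y.size();
  NumericMatrix g(n, m);
  fill_cost(x, y, window, g);
  double d = g(n - 1, m - 1);

  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  pi.push_back(i); pj.push_back(j);
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    double c = std::abs(x[i] - y[j]);
    double here = g(i, j);
    if (i > 0 && j > 0 &&
        std::abs(g(i - 1, j - 1) + 2.0 * c - here) <= eps * (1.0 + here)) {
      --i; --j;
    } else if (i > 0 && g(i - 1, j) < R_PosInf &&
               std::abs(g(i - 1, j) + c - here) <= eps * (1.0 + here)) {
      --i;
    } else if (j > 0 && g(i, j - 1) < R_PosInf &&
               std::abs(g(i, j - 1) + c - here) <= eps * (1.0 + here)) {
      --j;
    } else if (i > 0) {          // numeric fallback; should not trigger
      --i;
    } else {
      --j;
    }
    pi.push_back(i); pj.push_back(j);
  }
  const int L = pi.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {          // reverse to start at (1,1), 1-based
    path(k, 0) = pi[L - 1 - k] + 1;
    path(k, 1) = pj[L - 1 - k] + 1;
  }
  return List::create(_["distance"] = d, _["path"] = path);
}

// Pairwise DTW distances between the columns of a score matrix
// (visits x items).  Returns the symmetric items x items distance matrix.
// [[Rcpp::export(name = ".cpp_dtw_pairwise")]]
NumericMatrix cpp_dtw_pairwise(NumericMatrix scores, double window) {
  const int K = scores.ncol();
  NumericMatrix D(K, K);
  NumericMatrix g(scores.nrow(), scores.nrow());
  for (int a = 0; a < K; ++a) {
    for (int b = a + 1; b < K; ++b) {
      NumericVector x = scores(_, a), y = scores(_, b);
      fill_cost(x, y, window, g);
      double d = g(scores.nrow() - 1, scores.nrow() - 1);
      D(a, b) = d;
      D(b, a) = d;
    }
  }
  return D;
}
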