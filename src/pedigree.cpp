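#include <Rcpp.h>
using namespace Rcpp;

// Pedigree kernels. Animals are coded 1..n in an order where parents precede
// offspring; 0 denotes an unknown parent.

// Meuwissen & Luo (1992) inbreeding coefficients. Ancestor lists are kept
// as a descending linked list (`point`), giving O(total ancestors visited).
// [[Rcpp::export]]
NumericVector inbreeding_ml_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericVector F(n);
  std::vector<double> f(n + 1, 0.0);       // f[i] = F of animal i (1-based)
  std::vector<double> L(n + 1, 0.0), D(n + 1, 0.0);
  std::vector<int> point(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    int s = sire[i - 1], d = dam[i - 1];
    if (s >= i || d >= i) stop("pedigree not sorted parents-before-offspring");
    double Fs = s > 0 ? f[s] : 0.0, Fd = d > 0 ? f[d] : 0.0;
    if (s == 0 && d == 0) D[i] = 1.0;
    else if (s == 0) D[i] = 0.75 - 0.25 * Fd;
    else if (d == 0) D[i] = 0.75 - 0.25 * Fs;
    else D[i] = 0.5 - 0.25 * (Fs + Fd);
    if (s == 0 || d == 0) { f[i] = 0.0; continue; }
    double fi = -1.0;
    L[i] = 1.0;
    int j = i;
    while (j != 0) {
      int k = j;
      double r = 0.5 * L[k];
      // insert the larger parent id first: the list is descending and the
      // cursor k only moves forward
      int p1 = std::max(sire[k - 1], dam[k - 1]);
      int p2 = std::min(sire[k - 1], dam[k - 1]);
      if (p1 > 0) {
        while (point[k] > p1) k = point[k];
        L[p1] += r;
        if (p1 != point[k]) { point[p1] = point[k]; point[k] = p1; }
        if (p2 > 0) {
          while (point[k] > p2) k = point[k];
          L[p2] += r;
          if (p2 != point[k]) { point[p2] = point[k]; point[k] = p2; }
        }
      }
      fi += L[j] * L[j] * D[j];
      L[j] = 0.0;
      k = j;
      j = point[j];
      point[k] = 0;
    }
    f[i] = fi;
    F[i - 1] = fi;
  }
  for (int i = 0; i < n; ++i) F[i] = f[i + 1];
  return F;
}

// Mendelian sampling variances d_i used by A^{-1} and Colleau's method.
static std::vector<double> mendelian_d(const IntegerVector& sire,
                                       const IntegerVector& dam,
                                       const NumericVector& F) {
  const int n = sire.size();
  std::vector<double> d(n + 1);
  for (int i = 1; i <= n; ++i) {
    int s = sire[i - 1], dd = dam[i - 1];
    double Fs = s > 0 ? F[s - 1] : 0.0, Fd = dd > 0 ? F[dd - 1] : 0.0;
    if (s == 0 && dd == 0) d[i] = 1.0;
    else if (s == 0) d[i] = 0.75 - 0.25 * Fd;
    else if (dd == 0) d[i] = 0.75 - 0.25 * Fs;
    else d[i] = 0.5 - 0.25 * (Fs + Fd);
  }
  return d;
}

// Triplets of A^{-1} by Henderson's rules accounting for inbreeding.
// [[Rcpp::export]]
List a_inverse_triplets_cpp(IntegerVector sire, IntegerVector dam,
                            NumericVector F) {
  const int n = sire.size();
  std::vector<double> d = mendelian_d(sire, dam, F);
  std::vector<int> ti, tj; std::vector<double> tx;
  ti.reserve(9 * n); tj.reserve(9 * n); tx.reserve(9 * n);
  for (int i = 1; i <= n; ++i) {
    double a = 1.0 / d[i];
    int s = sire[i - 1], dd = dam[i - 1];
    ti.push_back(i); tj.push_back(i); tx.push_back(a);
    if (s > 0) {
      ti.push_back(i); tj.push_back(s); tx.push_back(-a / 2.0);
      ti.push_back(s); tj.push_back(i); tx.push_back(-a / 2.0);
      ti.push_back(s); tj.push_back(s); tx.push_back(a / 4.0);
    }
    if (dd > 0) {
      ti.push_back(i); tj.push_back(dd); tx.push_back(-a / 2.0);
      ti.push_back(dd); tj.push_back(i); tx.push_back(-a / 2.0);
      ti.push_back(dd); tj.push_back(dd); tx.push_back(a / 4.0);
    }
    if (s > 0 && dd > 0) {
      ti.push_back(s); tj.push_back(dd); tx.push_back(a / 4.0);
      ti.push_back(dd); tj.push_back(s); tx.push_back(a / 4.0);
    }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj), _["x"] = wrap(tx));
}

// Dense numerator relationship matrix by the tabular method (small
// pedigrees only: used by tests and candidate-subset construction).
// [[Rcpp::export]]
NumericMatrix a_dense_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i] - 1, d = dam[i] - 1; // -1 if unknown
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (s >= 0) v += 0.5 * A(j, s);
      if (d >= 0) v += 0.5 * A(j, d);
      A(i, j) = v; A(j, i) = v;
    }
    double diag = 1.0;
    if (s >= 0 && d >= 0) diag += 0.5 * A(s, d);
    A(i, i) = diag;
  }
  return A;
}

// Colleau (2002) indirect method: A %*% v in O(n) via A = T D T'.
static void colleau_Av(const IntegerVector& sire, const IntegerVector& dam,
                       const std::vector<double>& d,
                       std::vector<double>& w /* in: v, out: q */) {
  const int n = sire.size();
  // w <- T' v  (traverse youngest to oldest)
  for (int i = n; i >= 1; --i) {
    double r = 0.5 * w[i - 1];
    int s = sire[i - 1], dd = dam[i - 1];
    if (s > 0) w[s - 1] += r;
    if (dd > 0) w[dd - 1] += r;
  }
  // w <- D w
  for (int i = 1; i <= n; ++i) w[i - 1] *= d[i];
  // w <- T w  (oldest to youngest)
  for (int i = 1; i <= n; ++i) {
    int s = sire[i - 1], dd = dam[i - 1];
    double add = 0.0;
    if (s > 0) add += 0.5 * w[s - 1];
    if (dd > 0) add += 0.5 * w[dd - 1];
    w[i - 1] += add;
  }
}

// A[rows, cols] for a large pedigree without forming A.
// rows/cols are 1-based animal ids.
// [[Rcpp::export]]
NumericMatrix a_submatrix_cpp(IntegerVector sire, IntegerVector dam,
                              NumericVector F, IntegerVector rows,
                              IntegerVector cols) {
  const int n = sire.size();
  std::vector<double> d = mendelian_d(sire, dam, F);
  NumericMatrix out(rows.size(), cols.size());
  std::vector<double> w(n);
  for (int c = 0; c < cols.size(); ++c) {
    std::fill(w.begin(), w.end(), 0.0);
    w[cols[c] - 1] = 1.0;
    colleau_Av(sire, dam, d, w);
    for (int r = 0; r < rows.size(); ++r) out(r, c) = w[rows[r] - 1];
  }
  return out;
}
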