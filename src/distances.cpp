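#include <Rcpp.h>
using namespace Rcpp;

// Paths are stored as *columns* of d x n matrices so that each path is
// contiguous in memory. d = feature length (480 by default), n = paths.

static inline double pdist_cols(const double* a, const double* b, int d, double p) {
  double acc = 0.0;
  if (p == 2.0) {
    for (int k = 0; k < d; ++k) { double t = a[k] - b[k]; acc += t * t; }
    return std::sqrt(acc);
  }
  if (p == 1.0) {
    for (int k = 0; k < d; ++k) acc += std::fabs(a[k] - b[k]);
    return acc;
  }
  for (int k = 0; k < d; ++k) acc += std::pow(std::fabs(a[k] - b[k]), p);
  return std::pow(acc, 1.0 / p);
}

// Mirror-min dissimilarity matrix: D[i, j] = min(|v_i - v_j|_p, |v_i - m_j|_p)
// where m_j is the feature vector of path j's left-right mirror image.
// The reflection is a norm-preserving involution, so |v_i - m_j| and
// |v_j - m_i| agree up to rounding; both are evaluated and the smaller kept,
// which makes the matrix exactly symmetric and guarantees an exact zero for
// mirror duplicates whichever of the pair was stored mirrored.
// [[Rcpp::export]]
NumericMatrix mirror_min_dist_cpp(NumericMatrix vt, NumericMatrix mt, double p) {
  const int d = vt.nrow(), n = vt.ncol();
  if (mt.nrow() != d || mt.ncol() != n)
    stop("feature and mirror-feature matrices must have identical shape");
  NumericMatrix D(n, n);
  const double* v = vt.begin();
  const double* m = mt.begin();
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double val = pdist_cols(v + (size_t)i * d, v + (size_t)j * d, d, p);
      double d1 = pdist_cols(v + (size_t)i * d, m + (size_t)j * d, d, p);
      double d2 = pdist_cols(v + (size_t)j * d, m + (size_t)i * d, d, p);
      if (d1 < val) val = d1;
      if (d2 < val) val = d2;
      D(i, j) = val;
      D(j, i) = val;
    }
  }
  return D;
}

// Rectangular cross-distance (no mirror), used by the plain p-norm machinery.
// [[Rcpp::export]]
NumericMatrix cross_dist_cpp(NumericMatrix at, NumericMatrix bt, double p) {
  const int d = at.nrow(), na = at.ncol(), nb = bt.ncol();
  if (bt.nrow() != d) stop("feature lengths differ");
  NumericMatrix D(na, nb);
  const double* a = at.begin();
  const double* b = bt.begin();
  for (int j = 0; j < nb; ++j)
    for (int i = 0; i < na; ++i)
      D(i, j) = pdist_cols(a + (size_t)i * d, b + (size_t)j * d, d, p);
  return D;
}
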