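#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Smith-Waterman (Gotoh) over integer-encoded sequences.
// A gap of length k costs gap_open + k * gap_extend (BLAST-style
// existence/extension, default 11/1). Score floor 0. One optimal local
// alignment is reported with deterministic tie-breaking: the end cell is
// the first best-scoring cell in row-major order, and during traceback
// diagonal is preferred over up (gap in b) over left (gap in a); inside a
// gap state, closing the gap is preferred over extending it.
//
// a, b: 0-based integer codes indexing the substitution matrix.
// Returns score plus 0-based half-open aligned intervals on a and b.

// [[Rcpp::export(name = ".sw_align")]]
List sw_align(IntegerVector a, IntegerVector b, NumericMatrix subst,
              double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const int W = m + 1;
  const double NEG = -1e18;
  std::vector<double> H((n + 1) * W, 0.0), E((n + 1) * W, NEG),
      F((n + 1) * W, NEG);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j;
      const double e = std::max(H[idx - 1] - gap_open - gap_extend,
                                E[idx - 1] - gap_extend);
      const double f = std::max(H[idx - W] - gap_open - gap_extend,
                                F[idx - W] - gap_extend);
      double h = H[idx - W - 1] + subst(a[i - 1], b[j - 1]);
      if (f > h) h = f;
      if (e > h) h = e;
      if (h < 0.0) h = 0.0;
      E[idx] = e; F[idx] = f; H[idx] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  int i = bi, j = bj;
  const double eps = 1e-9;
  int state = 0;  // 0 = H, 1 = F (up, gap in b), 2 = E (left, gap in a)
  while (i > 0 && j > 0) {
    const int idx = i * W + j;
    if (state == 0) {
      if (H[idx] <= eps) break;
      const double d = H[idx - W - 1] + subst(a[i - 1], b[j - 1]);
      if (std::abs(H[idx] - d) < eps) { --i; --j; }
      else if (std::abs(H[idx] - F[idx]) < eps) state = 1;
      else state = 2;
    } else if (state == 1) {
      const double close = H[idx - W] - gap_open - gap_extend;
      const bool closes = std::abs(F[idx] - close) < eps;
      --i;
      if (closes) state = 0;
    } else {
      const double close = H[idx - 1] - gap_open - gap_extend;
      const bool closes = std::abs(E[idx] - close) < eps;
      --j;
      if (closes) state = 0;
    }
  }
  return List::create(_["score"] = best,
                      _["a_start"] = i, _["a_end"] = bi,
                      _["b_start"] = j, _["b_end"] = bj);
}

// Score-only variant (linear memory), used for reference self-scores.
// [[Rcpp::export(name = ".sw_score")]]
double sw_score(IntegerVector a, IntegerVector b, NumericMatrix subst,
                double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e18;
  std::vector<double> H(m + 1, 0.0), F(m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double diag = H[0];  // H[i-1][0] == 0
    double e = NEG;
    H[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      e = std::max(H[j - 1] - gap_open - gap_extend, e - gap_extend);
      F[j] = std::max(H[j] - gap_open - gap_extend, F[j] - gap_extend);
      double h = diag + subst(a[i - 1], b[j - 1]);
      if (F[j] > h) h = F[j];
      if (e > h) h = e;
      if (h < 0.0) h = 0.0;
      diag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}
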